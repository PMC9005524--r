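# hlaloh-msa v1
# kind: cDNA
# segments: exon1:210 exon2:210 exon3:210
A*01:01 CAATGAATACCGAGTACTCCCTCCTAAGGACATTTTTTGCTTGGATCTTGTAATTGACAAACCAGAACTAGATGACCAGTATCGAAGGCAAAGATGTACTTCATATTCGCGCGTACATACCTGGATGTGATGGGATTGCCAGCGAAGCTCGCCAGCCGGACCACGAACATACAGTATTCTGACACCACAGAACAATGTTCAAGGAGCTTAGATGTGGCTAGGTTTCTAATAGCGCAAGCGGACGTGCCGCACTCTGACAACCACGTTGATTGTTTGGATCCATTGAAATCGTGAAGTTCCTCTGAATGGGTCACGTCGGCGATTTGTGGGCTCTATGCCTCCTTCGAATTTCTAACTGCAACCGTATACTCAAGTGCCTGGTATAATGGATCCAGCAGACCATTGAGTGGCGACCGGCAACAAGAACTTAAAGTAGGACGAGGTGAACACTAATGACCCAGACGTCTATTTCATTGTTGCCTGGCGCAGACGCTTGTGACCAATCCATCCAAGCACTGATATCAGTCAAGGCTGAGCAAGGGGTTGTCCCGGGCAAAAACGAGATTACCCGAAACGTCTAGGCGATCCACTGCTACGTTCTTACAGCCCGCAACGCGCTTCCGAGCCACT
A*01:01:02 ------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------
A*01:02 ----T----------------------------------------------------------------------------------------C--------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------C-----------------------------------------------------------------------------------GT----------------------------------------------------------T-----------------------------------------
A*02:01 --------T--------------------------------------------------------------------------A-------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------C--------------T----------------------------------------------------------------------------T---------------------------C-----------------------------T----------------------------------------------------------------------------
A*03:01 --------------------------------------------------------------------------C---------------------------------------------G--------------------T----------------------------------------------------------------------------------------------------------------------------------------------A---------------------------------------------------------------------C-------------------G--------------------------------------------G---------C-------------------------------------------------------T-------------------------------------------------------------------------------------------------------------------C----------------------------
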