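# hlaloh-msa v1
# kind: gDNA
# segments: exon1:210 intron1:120 exon2:210 intron2:120 exon3:210
A*01:01 CAATGAATACCGAGTACTCCCTCCTAAGGACATTTTTTGCTTGGATCTTGTAATTGACAAACCAGAACTAGATGACCAGTATCGAAGGCAAAGATGTACTTCATATTCGCGCGTACATACCTGGATGTGATGGGATTGCCAGCGAAGCTCGCCAGCCGGACCACGAACATACAGTATTCTGACACCACAGAACAATGTTCAAGGAGCTTATGTATATCTTGTGAAACAATCTGTAACACTCACGGATAATCGGTATAGATCAAGAAAAGTCTTAGCGGGACCCGTCATATGTCCGGACTCTAGGCTCAGCTGGGAGCGCGTTAGTGTCGTGATGTGGCTAGGTTTCTAATAGCGCAAGCGGACGTGCCGCACTCTGACAACCACGTTGATTGTTTGGATCCATTGAAATCGTGAAGTTCCTCTGAATGGGTCACGTCGGCGATTTGTGGGCTCTATGCCTCCTTCGAATTTCTAACTGCAACCGTATACTCAAGTGCCTGGTATAATGGATCCAGCAGACCATTGAGTGGCGACCGGCAATCACATTTTGTTTGCAGTTACGCCTGAGCGAAGGGTATCTCGCACAAGAATGTCGGGAGGTGCAGCACAGAGCGCGAAGTTACAGTATCGTCGGACGCGTCAGCTTAACAGCTGCGCACCCAAGAACTTAAAGTAGGACGAGGTGAACACTAATGACCCAGACGTCTATTTCATTGTTGCCTGGCGCAGACGCTTGTGACCAATCCATCCAAGCACTGATATCAGTCAAGGCTGAGCAAGGGGTTGTCCCGGGCAAAAACGAGATTACCCGAAACGTCTAGGCGATCCACTGCTACGTTCTTACAGCCCGCAACGCGCTTCCGAGCCACT
A*01:01:02 ------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------************************************************************************************************************************------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------
A*01:02 ----T----------------------------------------------------------------------------------------C-----------------------------------------------------------------------------------------------------------------------------------------------------------------G----------C----------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------G-------------A-------T-------------------------------------T----------------------------------------------------******************************************************************************************************************************************************************************************************************
A*02:01 --------T--------------------------------------------------------------------------A------------------------------------------------------------------------------------------------------------------------------------------------------------------G-----------------------------------------------------------G------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------C--------------T--------------T----G-------------------------------------------------------------------------T------------------------------------------------------------------------------------------------------T---------------------------C-----------------------------T----------------------------------------------------------------------------
A*03:01 --------------------------------------------------------------------------C---------------------------------------------G--------------------T----------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------------A---------------------------------------------------------------------C-------------------G--------------------------------------------G-----------A---------------------------------------------------------T-----------------------------------------------------------C-------------------------------------------------------T-------------------------------------------------------------------------------------------------------------------C----------------------------
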