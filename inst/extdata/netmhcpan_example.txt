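# NetMHCpan version 4.1b
# Input is in PEPTIDE format
# Binding affinity prediction enabled
---------------------------------------------------------------------------------------------------------------------------
 Pos         MHC        Peptide      Core Of Gp Gl Ip Il        Icore        Identity  Score_EL %Rank_EL  Score_BA %Rank_BA  Aff(nM) BindLevel
---------------------------------------------------------------------------------------------------------------------------
   1 HLA-A*02:01      HMTEVVRHC HMTEVVRHC  0  0  0  0  0    HMTEVVRHC        PEPLIST  0.104200   2.1160  0.425100   1.9000   350.40 <= WB
   1 HLA-A*02:01      VVRHCPHHE VVRHCPHHE  0  0  0  0  0    VVRHCPHHE        PEPLIST  0.000310  45.0000  0.101200  35.0000 18950.20
   1 HLA-B*07:02      HMTEVVRHC HMTEVVRHC  0  0  0  0  0    HMTEVVRHC        PEPLIST  0.201100   0.9500  0.551200   0.8000    42.70 <= SB
   1 HLA-B*07:02      VVRHCPHHE VVRHCPHHE  0  0  0  0  0    VVRHCPHHE        PEPLIST  0.001200  30.1000  0.150300  28.0000  9620.00
---------------------------------------------------------------------------------------------------------------------------
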