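>JIP3_HUMAN_NTERM first_residue=1 synthetic stand-in for NP_055948.2 residues 1-187
MAEISSVEYTDLHGSKVRSEPAAVAEQKVKQLAGEIYSKFEELIGSYDETVVEKLMPEVV
EVLEKLEQVLWENQEHEELEEKVRELKEEIEYLEEKVKQLQKENRSLERRINKLRQEVYT
LENKLQEMKDEIEALEEKVKQLQKELRSLERRINKLRQEVATLENKKQELKDEIEALEEK
VKQLQKE
>JIP4_HUMAN_NTERM first_residue=1 synthetic stand-in for NP_001123999.1 residues 1-182
MADLSAEYEVSDLHRTASVAEQRVKQLAGEIYAKFEELIASYDETVVDKLMPEVVQVLER
LEEVLWENQEHEDLEEKVKELKEEIEFLEEKVRQLQKDNRSLEKRINKLKQEVYSLENKL
EEMKDDIEALEDKVKQLEKELRALERRISKLRQDVATLESKKQELRDEIESLEEKSKQLQ
KE
>JIP3_MOUSE_CONSTRUCT first_residue=22 synthetic stand-in for NP_038959.2 residues 22-187 (K30R vs human)
AAVAEQKVRQLAGEIYSKFEELIGSYDETVVEKLMPEVVEVLEKLEQVLWENQEHEELEE
KVRELKEEIEYLEEKVKQLQKENRSLERRINKLRQEVYTLENKLQEMKDEIEALEEKVKQ
LQKELRSLERRINKLRQEVATLENKKQELKDEIEALEEKVKQLQKE
>HEPTAD_DEMO first_residue=1 synthetic (LEALEGK)x4 register demo
LEALEGKLEALEGKLEALEGKLEALEGK
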