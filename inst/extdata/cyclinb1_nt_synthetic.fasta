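>CCNB1_NT_synthetic synthetic stand-in for the cyclin B1 N-terminal 1-88 aa region (wild-type lysines)
MALRVTRNSKINAENKAKINMAGAKRVPTAPAATSKPGLRPRTALGDIGNKVSEQLQAKL
PLPKEAKPSKTGKVIDKKLPKPLEKVPM
>CCNB1_NT_K64_synthetic synthetic stand-in, all lysines to arginine except K64
MALRVTRNSRINAENRARINMAGARRVPTAPAATSRPGLRPRTALGDIGNRVSEQLQARL
PLPKEARPSRTGRVIDRRLPRPLERVPM
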