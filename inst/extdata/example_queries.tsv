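EX1	Search for liver cancer gene expression datasets
EX2	find datasets of gut microbiome in colitis
EX3	looking for heart failure arrhythmia data
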