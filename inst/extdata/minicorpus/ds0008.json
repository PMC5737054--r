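{"title": "Type 2 diabetes plasma metabolomics",
 "description": "Mass spectrometry metabolome profiles and blood glucose measurements from a prospective cohort.",
 "metadata": {"organism": "Homo sapiens", "assay": "LC-MS",
   "keywords": ["diabetes mellitus", "insulin resistance", "metabolomics"]}}
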