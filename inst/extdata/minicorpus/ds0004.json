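{"title": "Breast cancer somatic mutation catalogue",
 "description": "Whole exome sequencing of triple negative breast neoplasms with matched germline samples.",
 "metadata": {"organism": "Homo sapiens", "assay": "WES",
   "keywords": ["carcinoma", "mutation", "tumor suppressor"]}}
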