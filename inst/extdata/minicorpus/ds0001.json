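{"title": "Hepatocellular carcinoma gene expression profiles",
 "description": "RNA sequencing of liver tumor and adjacent normal tissue from 40 patients with hepatocellular carcinoma.",
 "metadata": {"organism": "Homo sapiens", "assay": "RNA-seq",
   "keywords": ["liver", "neoplasms", "transcriptome"]}}
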