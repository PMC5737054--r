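{"title": "Gut microbiota in inflammatory bowel disease",
 "description": "16S rRNA amplicon survey of the gastrointestinal microbiome in Crohn disease and ulcerative colitis cohorts.",
 "metadata": {"organism": "human gut metagenome", "assay": "amplicon sequencing",
   "keywords": ["microbiota", "dysbiosis", "colitis"]}}
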