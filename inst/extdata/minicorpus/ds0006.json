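{"title": "Influenza A virus replication kinetics",
 "description": "Viral load time series and host transcriptome response in infected airway epithelial cell cultures.",
 "metadata": {"organism": "Influenza A virus", "assay": "qPCR",
   "keywords": ["orthomyxoviridae", "virus replication", "host response"]}}
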