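# Common lead-in words and phrases stripped from raw queries before
# tokenization (whole-word regex matches on the lowercased query).
# This list is configuration: edit freely or pass your own file.
search for
searching for
looking for
look for
find all
find
show me
give me
i need
i want
datasets of
datasets on
datasets about
datasets
dataset of
dataset
data on
data about
data related to
related to
regarding
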