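# Synthetic example parameters: collapse well-supported all-Metazoa and
# all-Viridiplantae clades down to 2 representatives each; any other
# category sharing a genus (rank 4) is trimmed to 2 as well.
threshold	0.8
rule	Metazoa	2	2
rule	Viridiplantae	2	2
default	4	2
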