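# Example biotinpaint run configuration (key: value; # starts a comment).
# Paths are resolved relative to the working directory.
fasta: inputs/proteome.fasta
sites: inputs/sites.tsv
tracks: inputs/tracks.tsv
tmt: inputs/tmt.tsv
go_annotations: inputs/go_annotations.tsv
go_bias: inputs/go_bias.tsv
go_biotinome: inputs/go_biotinome.tsv
out_dir: results
caller: VSL2b          # a predictor label, union, or consensus
quorum: 0.75           # consensus quorum fraction
threshold: 0.5         # disorder-probability binarization cutoff
alternative: two.sided # or greater
pool: biotinome        # null-rate pooling scope; or proteome
pseudo_count: 0.5      # log2 transform offset for biotin counts
alpha: 0.05            # kinetics significance threshold
analyses: enrichment, association, classes, ptm, go, timecourse
seed: 1
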