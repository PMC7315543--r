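# Example control file.  Copy this file together with example_tree.nwk into
# a working directory and run:
#   Rscript <path-to-package>/cli/simulate-genomes example.ctl
tree = example_tree.nwk
L = 30000
gc = 0.45
model = K2P
kappa = 1.6
codon_rates = 0.15, 0.07, 0.78
rho = 0.5
delta = 100
bias = off
gain_rate = 0.1
loss_rate = 0.1
gene_length = 999
scale = 1.0
seed = 42
output_dir = example_out
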