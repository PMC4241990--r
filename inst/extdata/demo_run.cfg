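# Bundled end-to-end demo: simulate a host invaded by a virus, then
# rediscover, reassemble, annotate and profile it.
#   Rscript inst/scripts/evepipe.R all --config inst/extdata/demo_run.cfg \
#       --outdir demo_out
stages = simulate,search,consensus,annotate,landscape
seed = 1
outdir = paleovir_demo
host_size = 40000
n_host_seqs = 2
n_insertions = 12
substitution_rate = 0.03
ta_bias = 0.3
join_distance = 1000
n_random = 99
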