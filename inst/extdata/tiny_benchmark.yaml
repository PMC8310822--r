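# Tiny deterministic benchmark: classical filters on two small phantoms.
input: phantom
n_images: 2
image_size: 96
dose_levels: [0.5, 0.05]
methods: [noisy, median, gaussian, wiener]
reference_method: gaussian
baseline_noise_sd: 10
out_dir: ldct-tiny-benchmark
image_format: tiff16
write_images: false
seed: 1
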