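Place the deposited 112-species branch-measurement CSV here as
dataset_s1.csv (figshare doi 10.6084/m9.figshare.30569648) to enable the
empirical-data acceptance tests; see tests/testthat/test-acceptance.R.
Nothing in this directory is required for the rest of the package.
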