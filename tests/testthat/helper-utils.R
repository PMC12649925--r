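# Access to internal seeding helpers so tests can reproduce the exact
# sub-streams the package derives from a top-level seed.
sub_seed_test <- function(seed, index) mlhgrn:::sub_seed(seed, index)

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
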