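## internal helpers

# Counter-based seed derivation so per-(gene, feature) permutation streams do
# not depend on iteration order. A small multiplicative string hash folded
# into [0, 2^31 - 2].
deriveSeed <- function(master, ...) {
  h <- as.double(master %% 2147483647L)
  for (tok in as.character(list(...))) {
    for (cp in utf8ToInt(tok)) h <- (h * 31 + cp) %% 2147483647
    h <- (h * 131 + 17) %% 2147483647
  }
  as.integer(h)
}

# Pseudocount permutation p-value: never 0, bounded below by 1/(n+1).
permPvalue <- function(nExtreme, nPerm) (1 + nExtreme) / (1 + nPerm)

# run expr with a local RNG state restored afterwards
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

stopIfNot <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
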