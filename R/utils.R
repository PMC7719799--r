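# Internal helpers: seeded evaluation, substream derivation, id handling.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers never perturb the
#' caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Derive a named substream seed from a master seed
#'
#' Small integer mix keeping results in [0, 2^31 - 2]; each (label, index)
#' pair gets its own reproducible stream so stages can be re-run in
#' isolation.
#' @noRd
sub_seed <- function(seed, label, index = 0L) {
  chars <- utf8ToInt(label)
  h <- sum(chars * seq_along(chars)) %% 1048573
  as.integer((abs(as.numeric(seed)) * 48271 + h * 1009 + abs(as.numeric(index)) * 7919) %%
               2147483646)
}

# Composite clonotype id used for joins; \x1f never occurs in gene names or
# nucleotide strings.
clone_id <- function(v_call, j_call, junction) {
  paste(v_call, j_call, junction, sep = "\x1f")
}

is_nt_string <- function(x) {
  !is.na(x) & nzchar(x) & !grepl("[^ACGT]", x)
}

random_nt <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Substitute one random position of each string with a different base.
corrupt_nt <- function(x) {
  n <- length(x)
  if (n == 0L) return(x)
  len <- nchar(x)
  pos <- floor(runif(n) * len) + 1L
  cur <- substr(x, pos, pos)
  alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")[cur]
  pick <- floor(runif(n) * 3) + 1L
  substr(x, pos, pos) <- substr(alt, pick, pick)
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
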