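# Internal helpers.

# Run code with a fixed RNG seed, restoring the caller's RNG state after.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

.rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.revcomp <- function(s) {
  as.character(reverseComplement(DNAString(s)))
}

# Substitute `rate` fraction of positions with a different random base.
.mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  n <- nchar(s)
  k <- rbinom(1L, n, rate)
  if (k == 0L) return(s)
  pos <- sample.int(n, k)
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    cur <- v[p]
    alt <- bases[bases != cur]
    v[p] <- if (length(alt) == 3L) alt[sample.int(3L, 1L)] else
      bases[sample.int(4L, 1L)]
  }
  paste(v, collapse = "")
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
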