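# Independent oracles and shared fixture builders for the test suite.

# Exhaustive enumeration of all monotone label chains (index steps <= delta
# on each map), scored as: B per matched pair, minus sizing cost
# (x - y)^2 / (v (x + y) + 1) per transition, minus p_miss per label merged
# over. Free ends. Independent of the package's DP implementation.
brute_map_score <- function(q, r, v, B, p_miss, delta) {
  n <- length(q); m <- length(r)
  best <- -Inf
  rec <- function(i, j, sc) {
    if (sc > best) best <<- sc
    for (di in 1:delta) {
      i2 <- i + di
      if (i2 > n) break
      x <- q[i2] - q[i]
      for (dj in 1:delta) {
        j2 <- j + dj
        if (j2 > m) break
        y <- r[j2] - r[j]
        cost <- (x - y)^2 / (v * (x + y) + 1)
        rec(i2, j2, sc + B - cost - p_miss * (di - 1 + dj - 1))
      }
    }
  }
  for (i in seq_len(n)) for (j in seq_len(m)) rec(i, j, B)
  best
}

# random label map with n labels, spacings 0.5-5 kb
random_labels <- function(n, min_gap = 500, max_gap = 5000) {
  cumsum(runif(n, min_gap, max_gap))
}

# N50 by direct definition over sorted prefix sums
brute_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  cs <- cumsum(s)
  s[which(cs >= sum(s) / 2)[1L]]
}

# evidence record with the requested per-database states; "sig" hits pass
# both coverages, "insig" hits fail coverage
make_evidence_record <- function(complete, um, up, pt, id = "p") {
  mk <- function(state) {
    switch(state,
      absent = c(NA_real_, NA_real_, NA_real_),
      insig = c(1e-20, 50, 50),
      sig = c(1e-20, 99, 99))
  }
  u <- mk(um); p2 <- mk(up); t2 <- mk(pt)
  data.frame(protein_id = id, complete = complete,
             um_evalue = u[1], um_qcov = u[2], um_scov = u[3],
             up_evalue = p2[1], up_qcov = p2[2], up_scov = p2[3],
             pt_evalue = t2[1], pt_qcov = t2[2], pt_scov = t2[3])
}

# small zero-noise benchmark world shared by several tests
make_world <- function(seed = 1, n_chrom = 2, chrom_length = 3e5,
                       error_plan = list(), coverage = 4L) {
  tr <- generateGenome(seed, n_chrom = n_chrom, chrom_length = chrom_length)
  fa <- fragmentAssembly(tr, error_plan = error_plan)
  ct <- simulateContigs(tr, n50_target = 4e4, coverage = coverage)
  list(truth = fa$truth, assembly = fa$assembly, contigs = ct$contigs,
       contig_truth = ct$placements)
}

read_fixture <- function(name) {
  read.delim(system.file("extdata", name, package = "gapsmith"),
             stringsAsFactors = FALSE, check.names = FALSE)
}
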