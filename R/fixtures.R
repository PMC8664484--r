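# Deterministic synthetic-data generators: truth genomes, gapped draft
# assemblies with planted errors, simulated long-read contigs, and simulated
# nick-site optical maps. Every stochastic draw comes from one RNG stream
# seeded explicitly, so identical calls are byte-identical.

#' Generate a repeat-rich synthetic truth genome
#'
#' Emulates a Triticeae-like chromosome: a small library of repeat monomers
#' (LTR-retrotransposon-like 5-8 kb, MITE-like 100-500 bp) is copy-pasted
#' with 1-5% per-copy divergence into a random background until the target
#' interspersed-repeat fraction is reached, and tandem-repeat blocks
#' (10-200 bp monomers arrayed to 2-10 kb) are overwritten at a Poisson rate
#' per Mb. The default repeat fraction matches the ~84% repeat content
#' typical of these genomes.
#'
#' @param seed Integer seed; the generator is byte-identical per seed.
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Chromosome length in bp (`>= 10000`).
#' @param tandem_block_rate Expected tandem-repeat blocks per Mb.
#' @param repeat_fraction Target fraction of interspersed repeat bp (0-1).
#' @return A [SyntheticTruth-class] with the genome and a `features` table of
#'   tandem blocks; layout/gap/error slots are empty until
#'   [fragmentAssembly()] is applied.
#' @examples
#' tr <- generateGenome(1, n_chrom = 1, chrom_length = 20000)
#' truthGenome(tr)
#' @export
generateGenome <- function(seed, n_chrom = 2L, chrom_length = 1e6,
                           tandem_block_rate = 5, repeat_fraction = 0.844) {
  if (chrom_length < 1e4) .stopf("chrom_length must be >= 10 kb")
  if (n_chrom < 1L) .stopf("n_chrom must be >= 1")
  if (!is.finite(tandem_block_rate) || tandem_block_rate < 0)
    .stopf("tandem_block_rate must be finite and non-negative")
  if (!is.finite(repeat_fraction) || repeat_fraction < 0 ||
      repeat_fraction > 1)
    .stopf("repeat_fraction must be in [0, 1]")
  .with_seed(seed, {
    # each LTR-like monomer carries one nick-site motif at a fixed offset
    # (mapping chemistries are chosen for adequate genome-wide label
    # density, and real LTR families carry recognition sites); per-copy
    # divergence still destroys some sites, so density varies realistically
    implant <- function(s) {
      motif <- if (runif(1L) < 0.5) "GCTCTTC" else "GAAGAGC"
      at <- sample.int(nchar(s) - 7L, 1L)
      substr(s, at, at + 6L) <- motif
      s
    }
    monomers <- c(
      lapply(lapply(sample(5000:8000, 3L, replace = TRUE), .rand_seq),
             implant),
      lapply(sample(100:500, 4L, replace = TRUE), .rand_seq)
    )
    tand_monomers <- lapply(sample(10:200, 4L, replace = TRUE), .rand_seq)
    chroms <- character(n_chrom)
    feats <- list()
    for (ci in seq_len(n_chrom)) {
      pieces <- character()
      tot <- 0; rep_bp <- 0
      while (tot < chrom_length) {
        if (rep_bp < repeat_fraction * max(tot, 1)) {
          m <- monomers[[sample.int(length(monomers), 1L)]]
          p <- .mutate_seq(m, runif(1L, 0.01, 0.05))
          rep_bp <- rep_bp + nchar(p)
        } else {
          p <- .rand_seq(sample(500:3000, 1L))
        }
        pieces <- c(pieces, p)
        tot <- tot + nchar(p)
      }
      s <- substr(paste(pieces, collapse = ""), 1L, chrom_length)
      # overwrite tandem blocks (keeps length exact, blocks whole)
      n_tand <- rpois(1L, tandem_block_rate * chrom_length / 1e6)
      placed <- IRanges()
      for (ti in seq_len(n_tand)) {
        mono <- tand_monomers[[sample.int(length(tand_monomers), 1L)]]
        blen <- sample(2000:10000, 1L)
        block <- .mutate_seq(
          substr(strrep(mono, ceiling(blen / nchar(mono))), 1L, blen),
          runif(1L, 0.01, 0.03))
        ok <- FALSE
        for (try in 1:50) {
          st <- sample.int(chrom_length - blen - 1L, 1L)
          cand <- IRanges(st, st + blen - 1L)
          if (!length(findOverlaps(cand, placed))) { ok <- TRUE; break }
        }
        if (!ok) next
        placed <- c(placed, cand)
        substr(s, st, st + blen - 1L) <- block
        feats[[length(feats) + 1L]] <- data.frame(
          chrom = paste0("chr", ci), start = st, end = st + blen - 1L,
          type = "tandem_block")
      }
      chroms[ci] <- s
    }
    names(chroms) <- paste0("chr", seq_len(n_chrom))
    new("SyntheticTruth",
        genome = DNAStringSet(chroms),
        segment_layout = data.frame(),
        gap_truth = data.frame(),
        planted_errors = data.frame(),
        features = if (length(feats)) do.call(rbind, feats) else
          data.frame(chrom = character(), start = integer(),
                     end = integer(), type = character()),
        seed = as.integer(seed))
  })
}

# draw non-overlapping gap intervals respecting margins and tandem avoidance
.draw_gap_positions <- function(L, spans, feats, margin = 5000L,
                                min_sep = 3000L) {
  n <- length(spans)
  if (n == 0L) return(integer())
  for (try in 1:200) {
    pos <- sort(sample.int(L - 2L * margin, n) + margin)
    iv_end <- pos + spans - 1L
    if (any(iv_end > L - margin)) next
    if (n > 1L && any(pos[-1L] - iv_end[-n] < min_sep)) next
    if (nrow(feats)) {
      gr <- IRanges(pmax(1L, pos - min_sep), iv_end + min_sep)
      fr <- IRanges(feats$start, feats$end)
      if (length(findOverlaps(gr, fr))) next
    }
    return(pos)
  }
  .stopf("could not place %d gaps on a %d bp chromosome", n, L)
}

#' Fragment a truth genome into a gapped draft assembly
#'
#' Concatenates truth segments with N-runs: placeholder gaps emit exactly
#' 10/100/1000 Ns (provenance codes; the hidden true span is recorded
#' separately) and sized gaps emit as many Ns as the true span. 1000-N gaps
#' define scaffold joins; requested errors are planted afterwards: a scaffold
#' moved to another chromosome (`misplacement`), a scaffold
#' reverse-complemented in place (`inversion`), or an artificial segmental
#' duplication flanking a spurious 10-N gap (`flank_duplication`).
#'
#' @param truth A [SyntheticTruth-class] from [generateGenome()].
#' @param placeholder_mix Named proportions for the `"10"`, `"100"`,
#'   `"1000"` placeholder classes; must sum to 1.
#' @param gap_rate Placeholder gaps per Mb (density; the class mix is
#'   `placeholder_mix`).
#' @param sized_gap_rate Sized gaps per Mb.
#' @param error_plan List of planted errors, each a list with `kind` in
#'   `"misplacement"`, `"inversion"`, `"flank_duplication"` and optional
#'   coordinates (`chrom`, `scaffold`, `target_chrom`, `position`,
#'   `dup_length`); unspecified coordinates are drawn from the stream.
#' @param seed Integer seed (defaults to `truth@seed + 1`).
#' @return A list with `assembly` (an [Assembly-class]) and `truth` (the
#'   input [SyntheticTruth-class] with layout, gap and error registries
#'   filled in, in draft coordinates).
#' @export
fragmentAssembly <- function(truth,
                             placeholder_mix = c("10" = 0.7, "100" = 0.15,
                                                 "1000" = 0.15),
                             gap_rate = 20, sized_gap_rate = 2,
                             error_plan = list(),
                             seed = truth@seed + 1L) {
  stopifnot(is(truth, "SyntheticTruth"))
  if (abs(sum(placeholder_mix) - 1) > 1e-9)
    .stopf("placeholder_mix proportions must sum to 1")
  mix_n <- as.integer(names(placeholder_mix))
  if (!all(mix_n %in% c(10L, 100L, 1000L)))
    .stopf("placeholder_mix names must be 10/100/1000")
  for (e in error_plan) {
    if (!is.list(e) || is.null(e$kind) ||
        !e$kind %in% c("misplacement", "inversion", "flank_duplication"))
      .stopf("error_plan entries need kind misplacement/inversion/flank_duplication")
    if (!is.null(e$chrom) && !e$chrom %in% names(truth@genome))
      .stopf("error_plan chrom '%s' not in genome", e$chrom)
    if (!is.null(e$position)) {
      L <- Biostrings::width(truth@genome)[match(e$chrom, names(truth@genome))]
      if (is.na(L) || e$position < 1 || e$position > L)
        .stopf("error_plan position outside genome")
    }
  }
  .with_seed(seed, {
    gseq <- as.character(truth@genome)
    feats <- truth@features
    tabs <- list()  # per-chrom piece tables
    for (cn in names(gseq)) {
      L <- nchar(gseq[[cn]])
      fts <- feats[feats$chrom == cn, , drop = FALSE]
      n_ph <- rpois(1L, gap_rate * L / 1e6)
      n_sz <- rpois(1L, sized_gap_rate * L / 1e6)
      emit <- c(mix_n[sample.int(length(mix_n), n_ph, replace = TRUE,
                                 prob = placeholder_mix)],
                rep(NA_integer_, n_sz))
      span_pool <- setdiff(50:2000, c(100L, 1000L))
      spans <- sample(span_pool, n_ph + n_sz, replace = TRUE)
      ord <- sample.int(n_ph + n_sz)  # interleave classes along the chrom
      emit <- emit[ord]; spans <- spans[ord]
      pos <- .draw_gap_positions(L, spans, fts)
      o <- order(pos); pos <- pos[o]; emit <- emit[o]; spans <- spans[o]
      emit[is.na(emit)] <- spans[is.na(emit)]  # sized gaps emit their span
      # alternate seq / gap pieces
      rows <- list()
      cur <- 1L
      for (i in seq_along(pos)) {
        rows[[length(rows) + 1L]] <- data.frame(
          kind = "seq", src_chrom = cn, src_start = cur,
          src_end = pos[i] - 1L, orientation = "+", emitted = NA_integer_,
          klass = NA_character_, true_span = NA_integer_, duplicate = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          kind = "gap", src_chrom = cn, src_start = pos[i],
          src_end = pos[i] + spans[i] - 1L, orientation = "+",
          emitted = emit[i], klass = classifyGap(emit[i]),
          true_span = spans[i], duplicate = FALSE)
        cur <- pos[i] + spans[i]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "seq", src_chrom = cn, src_start = cur, src_end = L,
        orientation = "+", emitted = NA_integer_, klass = NA_character_,
        true_span = NA_integer_, duplicate = FALSE)
      tabs[[cn]] <- do.call(rbind, rows)
    }
    planted <- list()
    for (e in error_plan) {
      tabs <- switch(e$kind,
        inversion = .plant_inversion(tabs, e, planted),
        misplacement = .plant_misplacement(tabs, e, planted),
        flank_duplication = .plant_duplication(tabs, e, feats, planted))
      planted <- attr(tabs, "planted")
    }
    .emit_draft(tabs, gseq, truth, planted, seed)
  })
}

# scaffold index per piece row: 1000-N gaps separate scaffolds
.scaffold_index <- function(tab) {
  sep <- tab$kind == "gap" & tab$klass == "placeholder1000"
  cumsum(c(FALSE, head(sep, -1L))) + 1L
}

.pick_scaffold <- function(tab, e, min_bp = 1.5e5) {
  sc <- .scaffold_index(tab)
  if (!is.null(e$scaffold)) return(e$scaffold)
  w <- ifelse(tab$kind == "seq", tab$src_end - tab$src_start + 1L,
              tab$emitted)
  bp <- tapply(w, sc, sum)
  elig <- as.integer(names(bp)[bp >= min_bp])
  # interior error targets keep at least one neighbour on each side when
  # possible, which exercises the harder case for placement validation
  if (length(elig) > 1L) elig <- setdiff(elig, 1L)
  if (!length(elig)) .stopf("no scaffold large enough to plant an error")
  elig[sample.int(length(elig), 1L)]
}

.plant_inversion <- function(tabs, e, planted) {
  cn <- if (!is.null(e$chrom)) e$chrom else
    names(tabs)[sample.int(length(tabs), 1L)]
  tab <- tabs[[cn]]
  si <- .pick_scaffold(tab, e)
  sc <- .scaffold_index(tab)
  idx <- which(sc == si & !(tab$kind == "gap" & tab$klass == "placeholder1000"))
  blk <- tab[rev(idx), , drop = FALSE]
  blk$orientation <- ifelse(blk$orientation == "+", "-", "+")
  tab[idx, ] <- blk
  tabs[[cn]] <- tab
  planted[[length(planted) + 1L]] <- data.frame(
    kind = "inversion", chrom = cn, scaffold = si,
    detail = NA_character_)
  attr(tabs, "planted") <- planted
  tabs
}

.plant_misplacement <- function(tabs, e, planted) {
  if (length(tabs) < 2L) .stopf("misplacement needs >= 2 chromosomes")
  cn <- if (!is.null(e$chrom)) e$chrom else
    names(tabs)[sample.int(length(tabs), 1L)]
  tab <- tabs[[cn]]
  si <- .pick_scaffold(tab, e)
  sc <- .scaffold_index(tab)
  idx <- which(sc == si & !(tab$kind == "gap" & tab$klass == "placeholder1000"))
  blk <- tab[idx, , drop = FALSE]
  # remove the scaffold plus one adjacent 1000-N join
  drop <- idx
  before <- idx[1L] - 1L
  after <- idx[length(idx)] + 1L
  if (before >= 1L) drop <- c(before, drop)
  else if (after <= nrow(tab)) drop <- c(drop, after)
  tab <- tab[-drop, , drop = FALSE]
  tabs[[cn]] <- tab
  tgt <- if (!is.null(e$target_chrom)) e$target_chrom else
    sample(setdiff(names(tabs), cn), 1L)
  ttab <- tabs[[tgt]]
  tsc <- .scaffold_index(ttab)
  nscaf <- max(tsc)
  jat <- sample.int(nscaf, 1L)  # the block becomes scaffold jat + 1
  join <- data.frame(kind = "gap", src_chrom = tgt, src_start = 1L,
                     src_end = 0L, orientation = "+", emitted = 1000L,
                     klass = "placeholder1000", true_span = 0L,
                     duplicate = FALSE)
  # every scaffold boundary must stay a single 1000-N run: interior
  # insertions ride after scaffold jat's trailing join and add a fresh
  # artifact join; appending at the chromosome end adds the join first
  if (jat < nscaf) {
    at <- max(which(tsc == jat))
    ins <- rbind(blk, join)
  } else {
    at <- nrow(ttab)
    ins <- rbind(join, blk)
  }
  tabs[[tgt]] <- rbind(ttab[seq_len(at), , drop = FALSE], ins,
                       ttab[-seq_len(at), , drop = FALSE])
  planted[[length(planted) + 1L]] <- data.frame(
    kind = "misplacement", chrom = tgt, scaffold = jat + 1L,
    detail = sprintf("from=%s;scaffold=%d", cn, si))
  attr(tabs, "planted") <- planted
  tabs
}

.plant_duplication <- function(tabs, e, feats, planted) {
  D <- if (!is.null(e$dup_length)) as.integer(e$dup_length) else
    sample(1500:4000, 1L)
  margin <- 3000L
  pool <- if (!is.null(e$chrom)) e$chrom else names(tabs)
  # eligible forward segments across all candidate chromosomes (earlier
  # planted errors may have flipped or removed everything on one of them)
  cand <- do.call(rbind, lapply(pool, function(nm) {
    tab <- tabs[[nm]]
    ri <- which(tab$kind == "seq" & tab$orientation == "+" &
                !tab$duplicate &
                (tab$src_end - tab$src_start + 1L) >= D + 2L * margin)
    if (length(ri)) data.frame(chrom = nm, row = ri) else NULL
  }))
  if (is.null(cand) || !nrow(cand))
    .stopf("no segment long enough for a flank duplication")
  pick <- cand[sample.int(nrow(cand), 1L), ]
  cn <- pick$chrom
  ri <- pick$row
  tab <- tabs[[cn]]
  row <- tab[ri, ]
  src <- row$src_chrom  # the row may source from another chromosome
  p <- if (!is.null(e$position)) as.integer(e$position) else {
    lo <- row$src_start + D + margin
    hi <- row$src_end - margin
    fts <- feats[feats$chrom == src, , drop = FALSE]
    p0 <- NA_integer_
    for (try in 1:100) {
      cp <- sample(seq(lo, hi), 1L)
      if (!nrow(fts) ||
          !length(findOverlaps(IRanges(cp - D - margin, cp + margin),
                               IRanges(fts$start, fts$end)))) {
        p0 <- cp; break
      }
    }
    if (is.na(p0)) .stopf("could not place flank duplication")
    p0
  }
  mk <- function(a, b, kind = "seq", emitted = NA_integer_,
                 klass = NA_character_, span = NA_integer_, dup = FALSE)
    data.frame(kind = kind, src_chrom = src, src_start = a, src_end = b,
               orientation = "+", emitted = emitted, klass = klass,
               true_span = span, duplicate = dup)
  repl <- rbind(
    mk(row$src_start, p),
    mk(p + 1L, p, kind = "gap", emitted = 10L, klass = "placeholder10",
       span = 0L),
    mk(p - D + 1L, p, dup = TRUE),
    mk(p + 1L, row$src_end))
  tab <- rbind(tab[seq_len(ri - 1L), , drop = FALSE], repl,
               tab[-seq_len(ri), , drop = FALSE])
  tabs[[cn]] <- tab
  planted[[length(planted) + 1L]] <- data.frame(
    kind = "flank_duplication", chrom = cn, scaffold = NA_integer_,
    detail = sprintf("position=%d;dup_length=%d", p, D))
  attr(tabs, "planted") <- planted
  tabs
}

.emit_draft <- function(tabs, gseq, truth, planted, seed) {
  seqs <- character(0)
  layout <- list(); gaps <- list()
  for (cn in names(tabs)) {
    tab <- tabs[[cn]]
    sc <- .scaffold_index(tab)
    parts <- character(nrow(tab))
    at <- 1L
    for (i in seq_len(nrow(tab))) {
      if (tab$kind[i] == "gap") {
        parts[i] <- strrep("N", tab$emitted[i])
        gaps[[length(gaps) + 1L]] <- data.frame(
          seq_id = cn, start = at, end = at + tab$emitted[i] - 1L,
          klass = tab$klass[i], emitted_n = tab$emitted[i],
          true_span = tab$true_span[i], source_chrom = tab$src_chrom[i],
          source_start = tab$src_start[i], source_end = tab$src_end[i])
        at <- at + tab$emitted[i]
      } else {
        s <- substr(gseq[[tab$src_chrom[i]]], tab$src_start[i], tab$src_end[i])
        if (tab$orientation[i] == "-") s <- .revcomp(s)
        parts[i] <- s
        layout[[length(layout) + 1L]] <- data.frame(
          seq_id = cn, seq_start = at, seq_end = at + nchar(s) - 1L,
          source_chrom = tab$src_chrom[i], source_start = tab$src_start[i],
          source_end = tab$src_end[i], orientation = tab$orientation[i],
          scaffold = sc[i], duplicate = tab$duplicate[i])
        at <- at + nchar(s)
      }
    }
    seqs[cn] <- paste(parts, collapse = "")
  }
  tr <- truth
  tr@segment_layout <- do.call(rbind, layout)
  tr@gap_truth <- if (length(gaps)) do.call(rbind, gaps) else data.frame()
  tr@planted_errors <- if (length(planted)) do.call(rbind, planted) else
    data.frame(kind = character(), chrom = character(),
               scaffold = integer(), detail = character())
  list(assembly = Assembly(seqs), truth = tr)
}

#' Simulate long-read contigs from a truth genome
#'
#' Draws `coverage` independent tilings of each truth chromosome with
#' exponentially distributed fragment lengths calibrated so the realized
#' contig N50 approximates `n50_target`, reverse-complements half the
#' contigs, applies uniform substitution errors, and (optionally) joins a
#' fraction of contigs to fragments from unlinked loci to simulate chimeras.
#'
#' @param truth A [SyntheticTruth-class].
#' @param n50_target Target contig N50 (bp).
#' @param error_rate Substitutions per bp, in `[0, 0.05]`.
#' @param chimera_rate Fraction of contigs made chimeric, in `[0, 1]`.
#' @param seed Integer seed.
#' @param coverage Number of independent tilings (fold coverage).
#' @return A list: `contigs` ([Biostrings::DNAStringSet]), `placements`
#'   (truth placements, 1-based), `chimeras` (junction registry).
#' @export
simulateContigs <- function(truth, n50_target = 5e4, error_rate = 0,
                            chimera_rate = 0, seed = truth@seed + 2L,
                            coverage = 3L) {
  stopifnot(is(truth, "SyntheticTruth"))
  if (error_rate < 0 || error_rate > 0.05)
    .stopf("error_rate must be in [0, 0.05]")
  if (chimera_rate < 0 || chimera_rate > 1)
    .stopf("chimera_rate must be in [0, 1]")
  .with_seed(seed, {
    gseq <- as.character(truth@genome)
    mean_len <- n50_target / 1.678  # N50 of Exp(m) tiling ~ 1.678 m
    contigs <- character(); plc <- list(); chim <- list()
    ctr <- 0L
    for (pass in seq_len(coverage)) {
      phase <- names(gseq)
      for (cn in phase) {
        L <- nchar(gseq[[cn]])
        cur <- 1L
        while (cur <= L) {
          len <- max(1000L, min(as.integer(rexp(1L, 1 / mean_len)), L - cur + 1L))
          ctr <- ctr + 1L
          id <- sprintf("ctg%05d", ctr)
          s <- substr(gseq[[cn]], cur, cur + len - 1L)
          ori <- if (runif(1L) < 0.5) "+" else "-"
          plc[[length(plc) + 1L]] <- data.frame(
            contig_id = id, source_chrom = cn, source_start = cur,
            source_end = cur + len - 1L, orientation = ori, part = 1L)
          if (runif(1L) < chimera_rate) {
            oc <- sample(names(gseq), 1L)
            oL <- nchar(gseq[[oc]])
            flen <- max(5000L, as.integer(len / 2))
            fst <- sample.int(max(1L, oL - flen), 1L)
            frag <- substr(gseq[[oc]], fst, fst + flen - 1L)
            chim[[length(chim) + 1L]] <- data.frame(
              contig_id = id, junction = nchar(s),
              left_chrom = cn, right_chrom = oc, right_start = fst)
            plc[[length(plc) + 1L]] <- data.frame(
              contig_id = id, source_chrom = oc, source_start = fst,
              source_end = fst + flen - 1L, orientation = "+", part = 2L)
            s <- paste0(s, frag)
          }
          if (ori == "-") s <- .revcomp(s)
          if (error_rate > 0) s <- .mutate_seq(s, error_rate)
          contigs[id] <- s
          cur <- cur + len
        }
      }
    }
    list(contigs = DNAStringSet(contigs),
         placements = do.call(rbind, plc),
         chimeras = if (length(chim)) do.call(rbind, chim) else
           data.frame(contig_id = character(), junction = integer(),
                      left_chrom = character(), right_chrom = character(),
                      right_start = integer()))
  })
}

#' Simulate consensus optical maps from sequences
#'
#' Labels every motif occurrence on either strand (positions are motif
#' starts in forward coordinates), merges labels closer than `resolution` to
#' their cluster midpoint, optionally splits the map at fragile sites
#' (opposite-strand occurrences within `fragile_window`, where molecules
#' break), then applies per-label dropout, spurious labels, and fragment
#' sizing noise with the given coefficient of variation.
#'
#' @param x A [Biostrings::DNAStringSet], [SyntheticTruth-class],
#'   [Assembly-class], or named character vector.
#' @param motif Nick-site recognition sequence (default Nt.BspQI GCTCTTC).
#' @param resolution Minimum resolvable label spacing (bp).
#' @param fragile_window Opposite-strand nick spacing (bp) below which the
#'   map breaks; `0` disables fragility.
#' @param sizing_cv Coefficient of variation of fragment sizing noise.
#' @param p_miss Per-label dropout probability.
#' @param false_per_100kb Spurious label rate per 100 kb.
#' @param seed Integer seed (only consulted when noise is requested).
#' @return A list of [LabelMap-class] objects; map ids are the sequence
#'   names, suffixed `_1`, `_2`, ... when fragility splits a map.
#' @export
simulateOpticalMap <- function(x, motif = "GCTCTTC", resolution = 1000,
                               fragile_window = 0, sizing_cv = 0,
                               p_miss = 0, false_per_100kb = 0, seed = 1L) {
  seqs <- .as_seq_set(x)
  stopifnot(nchar(motif) >= 4, p_miss >= 0, p_miss <= 1, sizing_cv >= 0,
            false_per_100kb >= 0)
  .with_seed(seed, {
    maps <- list()
    for (cn in names(seqs)) {
      s <- seqs[[cn]]
      L <- nchar(s)
      sites <- .nick_sites(s, motif)
      splits <- numeric(0)
      if (fragile_window > 0 && nrow(sites) > 1L) {
        d <- diff(sites$pos)
        opp <- sites$strand[-1L] != sites$strand[-nrow(sites)]
        frag <- which(d <= fragile_window & opp)
        splits <- (sites$pos[frag] + sites$pos[frag + 1L]) / 2
      }
      bounds <- c(0, splits, L)
      piece_id <- 0L
      for (b in seq_len(length(bounds) - 1L)) {
        lo <- bounds[b]; hi <- bounds[b + 1L]
        lab <- sites$pos[sites$pos > lo & sites$pos <= hi] - lo
        plen <- hi - lo
        lab <- .merge_labels(lab, resolution)
        if (p_miss > 0 && length(lab))
          lab <- lab[runif(length(lab)) >= p_miss]
        if (false_per_100kb > 0) {
          nf <- rpois(1L, false_per_100kb * plen / 1e5)
          if (nf > 0)
            lab <- sort(unique(c(lab, runif(nf, 1, plen))))
        }
        if (sizing_cv > 0 && length(lab)) {
          fr <- diff(c(0, lab, plen))
          fr <- pmax(1, fr * (1 + rnorm(length(fr), 0, sizing_cv)))
          lab <- cumsum(fr)[seq_along(lab)]
          plen <- sum(fr)
        }
        piece_id <- piece_id + 1L
        id <- if (length(bounds) > 2L) sprintf("%s_%d", cn, piece_id) else cn
        maps[[id]] <- new("LabelMap", map_id = id, length = plen,
                          labels = lab)
      }
    }
    maps
  })
}

.as_seq_set <- function(x) {
  if (is(x, "SyntheticTruth")) return(as.character(x@genome))
  if (is(x, "Assembly")) return(as.character(x@seqs))
  if (is(x, "DNAStringSet")) return(as.character(x))
  stopifnot(is.character(x), !is.null(names(x)))
  x
}
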