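# Independent brute-force oracles used to check the package implementations.
# These deliberately share no code with the package: plain loops and
# definitional formulas only.

rc_chr <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

rand_read <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

mutate_k <- function(seq, k) {
  # plant exactly k substitutions at distinct positions
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# Exhaustive Hamming scan over all offsets and both orientations, with the
# declared tie-break: fewest mismatches, then smallest offset, then forward
# before reverse.
oracle_find_bridge <- function(read, bridge, max_mm = 4L) {
  bw <- nchar(bridge)
  L <- nchar(read)
  none <- list(orientation = NA_character_, offset = NA_integer_,
               mismatches = NA_integer_)
  if (L < bw) return(none)
  pats <- c(forward = bridge, reverse = rc_chr(bridge))
  best <- NULL
  for (oi in 1:2) {
    pc <- strsplit(pats[[oi]], "")[[1]]
    for (off in 0:(L - bw)) {
      w <- strsplit(substr(read, off + 1, off + bw), "")[[1]]
      mm <- sum(w != pc)
      if (mm > max_mm) next
      better <- is.null(best) || mm < best$mism ||
        (mm == best$mism && off < best$off) ||
        (mm == best$mism && off == best$off && oi < best$oi)
      if (better) best <- list(oi = oi, off = off, mism = mm)
    }
  }
  if (is.null(best)) return(none)
  list(orientation = names(pats)[best$oi], offset = best$off,
       mismatches = best$mism)
}

# Width-w window enumeration applying the four site-calling rules with the
# same greedy order as the stated procedure.
oracle_call_sites <- function(scores, replicates, cfg) {
  w <- cfg$site_width
  flank <- (w - 1) %/% 2
  n_drop <- floor(cfg$score_percentile_drop * nrow(scores))
  o <- order(scores$score, scores$chrom, scores$pos)
  surv <- scores[setdiff(seq_len(nrow(scores)), o[seq_len(n_drop)]), ]
  surv <- surv[order(-surv$score, surv$chrom, surv$pos), ]
  pooled <- do.call(rbind, replicates)
  accepted <- list()
  for (i in seq_len(nrow(surv))) {
    c0 <- surv$pos[i]; cn <- surv$chrom[i]
    clash <- FALSE
    for (a in accepted)
      if (a$chrom == cn && abs(a$ctr - c0) < w) { clash <- TRUE; break }
    if (clash) next
    accepted[[length(accepted) + 1]] <- list(chrom = cn, ctr = c0)
  }
  keep <- list()
  for (a in accepted) {
    win <- (a$ctr - flank):(a$ctr + flank)
    covered <- length(unique(pooled$pos[pooled$chrom == a$chrom &
                                          pooled$pos %in% win]))
    support <- sum(vapply(replicates, function(r)
      any(r$chrom == a$chrom & r$pos %in% win), TRUE))
    if (covered >= cfg$min_covered_positions &&
        support >= cfg$min_replicate_support)
      keep[[length(keep) + 1]] <- data.frame(chrom = a$chrom,
                                             start = a$ctr - flank,
                                             end = a$ctr + flank + 1)
  }
  if (!length(keep))
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  out <- do.call(rbind, keep)
  out[order(out$chrom, out$start), ]
}

# Two-sided Fisher exact p by full hypergeometric enumeration over the
# conditional distribution with fixed margins (table layout rbind(c(a, c),
# c(b, d)), i.e. column-major a, b, c, d as fisher.test receives it).
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + c; r2 <- b + d; c1 <- a + b
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(xs, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments.
oracle_signed_rank_p <- function(x, y) {
  d <- x - y
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  r <- rank(abs(d))
  n <- length(d)
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  vs <- signs %*% r
  p_le <- mean(vs <= v_obs)
  p_ge <- mean(vs >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# O(n^2) definitional BH: q_i = min over p_j >= p_i of n * p_j / rank(p_j).
oracle_bh <- function(p) {
  n <- length(p)
  vapply(p, function(pi) {
    cand <- vapply(p[p >= pi], function(pj) n * pj / sum(p <= pj), 1)
    min(1, min(cand))
  }, 1)
}

# Small random score/replicate track pair for site-caller checks.
random_tracks <- function(n_pos = 30, span = 120) {
  pos <- sort(sample.int(span, n_pos))
  scores <- data.frame(chrom = "chr1", pos = pos, score = round(runif(n_pos), 3))
  reps <- lapply(1:5, function(i) {
    keep <- runif(n_pos) < 0.55
    data.frame(chrom = "chr1", pos = pos[keep],
               count = sample.int(3L, sum(keep), TRUE))
  })
  list(scores = scores, reps = reps)
}
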