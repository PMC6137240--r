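# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the aligner is a hand-written Gotoh DP, BH is the
# literal step-up rule, and the resampling oracle re-implements rarefaction
# from the Chao1 formula alone.

# Local (Smith-Waterman) alignment with affine gaps by full dynamic
# programming plus traceback. match +1, mismatch -1; a gap of length L costs
# 5 + 2*(L-1). Returns identity (matches / aligned columns) and overlap
# (aligned length of the shorter sequence / shorter length).
oracle_align <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  OPEN <- -5; EXT <- -2
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap consuming B
  F <- matrix(-Inf, n + 1, m + 1)  # gap consuming A
  best <- 0; bi <- 0; bj <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(E[i, j - 1] + EXT, H[i, j - 1] + OPEN)
      F[i, j] <- max(F[i - 1, j] + EXT, H[i - 1, j] + OPEN)
      s <- if (A[i - 1] == B[j - 1]) 1 else -1
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) { best <- H[i, j]; bi <- i; bj <- j }
    }
  }
  if (best == 0) return(c(identity = 0, overlap = 0))
  i <- bi; j <- bj; state <- "H"
  matches <- 0L; cols <- 0L; ei <- bi; ej <- bj
  repeat {
    if (state == "H") {
      if (H[i, j] == 0) break
      s <- if (A[i - 1] == B[j - 1]) 1 else -1
      if (H[i, j] == H[i - 1, j - 1] + s) {
        matches <- matches + (s == 1); cols <- cols + 1L
        i <- i - 1; j <- j - 1
      } else if (H[i, j] == E[i, j]) state <- "E"
      else state <- "F"
    } else if (state == "E") {
      cols <- cols + 1L
      if (E[i, j] == E[i, j - 1] + EXT) j <- j - 1
      else { j <- j - 1; state <- "H" }
    } else {
      cols <- cols + 1L
      if (F[i, j] == F[i - 1, j] + EXT) i <- i - 1
      else { i <- i - 1; state <- "H" }
    }
  }
  span_a <- ei - i; span_b <- ej - j
  shorter_span <- if (n <= m) span_a else span_b
  c(identity = matches / cols, overlap = shorter_span / min(n, m))
}

# Greedy dereplication using the oracle aligner for every pair, same order.
oracle_dereplicate <- function(seqs, id_thr = 0.95, ov_thr = 0.90) {
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  reps <- character(); rep_of <- character(length(seqs))
  for (i in seq_along(seqs)) {
    assigned <- NA_character_
    for (r in reps) {
      al <- oracle_align(seqs[[r]], seqs[[i]])
      if (al["identity"] > id_thr && al["overlap"] > ov_thr) {
        assigned <- r; break
      }
    }
    if (is.na(assigned)) { reps <- c(reps, names(seqs)[i]); assigned <- names(seqs)[i] }
    rep_of[i] <- assigned
  }
  data.frame(member_id = names(seqs), representative_id = rep_of,
             stringsAsFactors = FALSE)
}

# Literal step-up Benjamini-Hochberg.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# Independent with-replacement rarefaction of the Chao1 estimate at a fixed m.
oracle_rarefy_mean <- function(pres, m, reps) {
  n <- ncol(pres)
  est <- vapply(seq_len(reps), function(r) {
    draw <- sample.int(n, m, replace = TRUE)
    inc <- rowSums(pres[, draw, drop = FALSE] > 0)
    S <- sum(inc >= 1); f1 <- sum(inc == 1); f2 <- sum(inc == 2)
    S + f1 * (f1 - 1) / (2 * (f2 + 1))
  }, numeric(1))
  c(mean = mean(est), sd = sd(est))
}

random_seq <- function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                                collapse = "")

# plant n_sub substitutions at distinct random positions
mutate_seq <- function(s, n_sub) {
  v <- strsplit(s, "")[[1]]
  pos <- sample(length(v), n_sub)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}

# adjusted Rand index (independent of mclust, used when comparing labelings)
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}
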