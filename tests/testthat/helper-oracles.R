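# Independent brute-force oracles, written from first principles on purpose:
# they share no code with the implementation they check.

# average ranks, descending, by explicit counting
oracle_rank_desc <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n))
    r[i] <- sum(x > x[i]) + (sum(x == x[i]) + 1) / 2
  r
}

# tie-corrected Kendall's W from explicit rank sums and explicit tie groups
oracle_kendall_w <- function(mat) {
  m <- nrow(mat); n <- ncol(mat)
  ranks <- matrix(0, m, n)
  for (i in seq_len(m)) ranks[i, ] <- oracle_rank_desc(mat[i, ])
  R <- colSums(ranks)
  S <- sum((R - m * (n + 1) / 2)^2)
  Tsum <- 0
  for (i in seq_len(m)) {
    runs <- rle(sort(mat[i, ]))$lengths
    Tsum <- Tsum + sum(runs^3 - runs)
  }
  12 * S / (m^2 * (n^3 - n) - m * Tsum)
}

# per-indicator concentration statistics by explicit summation
oracle_indicator_stats <- function(scores, full_score) {
  n <- length(scores)
  M <- sum(scores) / n
  s <- if (n > 1) sqrt(sum((scores - M)^2) / (n - 1)) else 0
  list(M = M, sd = s, V = s / M, K = sum(scores == full_score) / n)
}

# minimal valid response table around a score matrix (experts x indicators)
responses_from_matrix <- function(mat, round = 1L, distributed = nrow(mat),
                                  familiarity = "familiar", band = "mid",
                                  config = panel_config()) {
  experts <- rownames(mat) %||% sprintf("e%02d", seq_len(nrow(mat)))
  inds <- colnames(mat) %||% sprintf("i%02d", seq_len(ncol(mat)))
  d <- expand.grid(expert_id = experts, indicator_id = inds,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$score <- as.vector(mat)
  d$familiarity <- familiarity
  d$jb_practical <- d$jb_theoretical <- d$jb_peers <- d$jb_insight <- band
  d <- d[!is.na(d$score), , drop = FALSE]
  response_set(d, round = round, distributed = distributed, config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random stats table with internally consistent Vj = sd/Mj
random_stats_table <- function(n, rng) {
  Mj <- stats::runif(n, 1, 10)
  sd <- stats::runif(n, 0, 3)
  structure(data.frame(
    indicator_id = sprintf("i%02d", seq_len(n)),
    m = 15L, Mj = Mj, sd = sd, Vj = sd / Mj,
    Kj = stats::runif(n), Cs = stats::runif(n), Ca = stats::runif(n),
    stringsAsFactors = FALSE
  ), class = "data.frame")
}
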