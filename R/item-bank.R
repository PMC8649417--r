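# Item bank generation and condition-specific item draws.

#' Truncated normal draws by rejection
#'
#' Simple rejection sampler used for item-parameter generation; all
#' truncation regions in this package retain most of the mass, so
#' acceptance rates are high.
#'
#' @param n number of draws.
#' @param mean,sd normal parameters.
#' @param lower,upper truncation bounds.
#' @return Numeric vector of length `n`.
#' @export
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(max(n - length(out), 16L) * 2L, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Generate an item bank
#'
#' Draws a bank of GRM items from the study's generating distributions.
#' Discriminations are uniform on \[1.7, 3.5\] (high) or \[0.5, 1.0\] (low).
#' Dichotomous thresholds are N(0.1, sd 1.3) truncated to \[-2.5, 2.4\].
#' Polytomous (five-category) first thresholds are N(-1, sd 1) truncated to
#' \[-3.5, 0.5\]; the remaining three are built by successively adding
#' N(0.8, sd 0.2) increments truncated to \[0.4, 1.2\], so the largest
#' threshold lies in \[0.1, 4.1\]. Uses the current R random number stream.
#'
#' @param item_type `"dichotomous"` or `"polytomous"`.
#' @param discrimination_level `"high"` or `"low"`.
#' @param size number of items (default 10000).
#' @return A `grm_item_bank`: data.frame with columns `item_id`, `V`, `a`,
#'   `b1`..`b4` (`NA` beyond `V - 1`), plus attributes `item_type` and
#'   `discrimination_level`.
#' @export
build_item_bank <- function(item_type = c("dichotomous", "polytomous"),
                            discrimination_level = c("high", "low"),
                            size = 10000L) {
  item_type <- match.arg(item_type)
  discrimination_level <- match.arg(discrimination_level)
  a <- if (discrimination_level == "high") stats::runif(size, 1.7, 3.5)
       else stats::runif(size, 0.5, 1.0)
  if (item_type == "dichotomous") {
    b <- cbind(rtrunc_norm(size, 0.1, 1.3, -2.5, 2.4), NA, NA, NA)
    V <- 2L
  } else {
    b1 <- rtrunc_norm(size, -1, 1, -3.5, 0.5)
    d2 <- rtrunc_norm(size, 0.8, 0.2, 0.4, 1.2)
    d3 <- rtrunc_norm(size, 0.8, 0.2, 0.4, 1.2)
    d4 <- rtrunc_norm(size, 0.8, 0.2, 0.4, 1.2)
    b <- cbind(b1, b1 + d2, b1 + d2 + d3, b1 + d2 + d3 + d4)
    V <- 5L
  }
  bank <- data.frame(item_id = seq_len(size), V = V, a = a,
                     b1 = b[, 1], b2 = b[, 2], b3 = b[, 3], b4 = b[, 4])
  structure(bank, item_type = item_type,
            discrimination_level = discrimination_level,
            class = c("grm_item_bank", "data.frame"))
}

# One bank row -> grm_item
.bank_item <- function(bank, i) {
  V <- bank$V[i]
  b <- as.numeric(bank[i, c("b1", "b2", "b3", "b4")])[seq_len(V - 1L)]
  grm_item(bank$a[i], b)
}

#' Draw a condition's item set from a bank
#'
#' Under `"diverse"` thresholds, items are a simple random sample without
#' replacement. Under `"homogeneous"`, a benchmark item is drawn first and
#' the remaining items are sampled from bank members whose every threshold
#' lies within 0.25 of the benchmark's corresponding threshold; if fewer
#' than `n_items - 1` such items exist, a new benchmark is drawn (up to
#' `max_restarts` times).
#'
#' @param bank a [build_item_bank()] result.
#' @param n_items number of items to draw.
#' @param thresholds_mode `"diverse"` or `"homogeneous"`.
#' @param max_restarts benchmark redraw cap for the homogeneous mode.
#' @return List of [grm_item()] with attribute `item_ids` (bank rows drawn).
#' @export
draw_items <- function(bank, n_items,
                       thresholds_mode = c("diverse", "homogeneous"),
                       max_restarts = 1000L) {
  thresholds_mode <- match.arg(thresholds_mode)
  stopifnot(inherits(bank, "grm_item_bank"), n_items <= nrow(bank))
  nb <- bank$V[1L] - 1L
  bmat <- as.matrix(bank[, c("b1", "b2", "b3", "b4")[seq_len(nb)], drop = FALSE])
  if (thresholds_mode == "diverse") {
    ids <- sample.int(nrow(bank), n_items)
  } else {
    ids <- NULL
    for (try in seq_len(max_restarts)) {
      bench <- sample.int(nrow(bank), 1L)
      ok <- rep(TRUE, nrow(bank))
      for (k in seq_len(nb))
        ok <- ok & abs(bmat[, k] - bmat[bench, k]) <= 0.25
      ok[bench] <- FALSE
      cand <- which(ok)
      if (length(cand) >= n_items - 1L) {
        ids <- c(bench, if (n_items > 1L) sample(cand, n_items - 1L))
        break
      }
    }
    if (is.null(ids))
      stop("homogeneous item draw infeasible after ", max_restarts,
           " benchmark restarts")
  }
  items <- lapply(ids, function(i) .bank_item(bank, i))
  attr(items, "item_ids") <- ids
  items
}
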