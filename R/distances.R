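# Pairwise nucleotide distances: p, Jukes-Cantor and Kimura 2-parameter.
# Sites where either sequence carries an ambiguous base are excluded
# pairwise. The corrected distances are undefined (saturated) when a log
# argument is <= 0.

.pair_site_counts <- function(s1, s2) {
  a <- strsplit(toupper(s1), "")[[1]]
  b <- strsplit(toupper(s2), "")[[1]]
  if (length(a) != length(b)) {
    abort("sequences must be equal length", class = "mhctsp_error")
  }
  keep <- a %in% NUC & b %in% NUC
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  diff <- a != b
  ts <- diff & is_transition(a, b)
  list(n = n, nd = sum(diff), nts = sum(ts), ntv = sum(diff) - sum(ts))
}

#' Pairwise nucleotide distance between two sequences
#'
#' Computes the proportion of differing sites `p`, the transition and
#' transversion proportions `P` and `Q`, and the Jukes-Cantor and Kimura
#' 2-parameter corrected distances. Sites with non-ACGT bases in either
#' sequence are excluded pairwise.
#'
#' @param s1,s2 Nucleotide strings of equal length.
#' @param model One of `"p"`, `"JC"`, `"K2"`; determines which distance must
#'   be defined for the call to succeed.
#' @param allow_saturated If `TRUE`, saturated pairs are returned with the
#'   corrected distance set to `NA` and `saturated = TRUE` instead of
#'   raising an error.
#' @return A one-row tibble with columns `n_sites`, `p`, `P`, `Q`, `d_jc`,
#'   `d_k2`, `d` (the distance under `model`) and `saturated`.
#' @export
pairwise_distance <- function(s1, s2, model = c("K2", "JC", "p"),
                              allow_saturated = FALSE) {
  model <- match.arg(model)
  cs <- .pair_site_counts(s1, s2)
  if (cs$n == 0L) abort("no comparable sites", class = "mhctsp_error")
  p <- cs$nd / cs$n
  P <- cs$nts / cs$n
  Q <- cs$ntv / cs$n
  arg_jc <- 1 - 4 * p / 3
  arg_k2a <- 1 - 2 * P - Q
  arg_k2b <- 1 - 2 * Q
  d_jc <- if (arg_jc > 0) -3 / 4 * log(arg_jc) else NA_real_
  d_k2 <- if (arg_k2a > 0 && arg_k2b > 0) {
    -0.5 * log(arg_k2a) - 0.25 * log(arg_k2b)
  } else {
    NA_real_
  }
  d <- switch(model, p = p, JC = d_jc, K2 = d_k2)
  saturated <- is.na(d)
  if (saturated && !allow_saturated) {
    abort(
      sprintf(
        "saturated pair under %s model (n=%d sites, %d transitions, %d transversions)",
        model, cs$n, cs$nts, cs$ntv
      ),
      class = "mhctsp_saturation"
    )
  }
  tibble(
    n_sites = cs$n, p = p, P = P, Q = Q,
    d_jc = d_jc, d_k2 = d_k2, d = d, saturated = saturated
  )
}

# Square distance matrix over the alignment's sequences. Saturated pairs
# become NA with attribute "saturated_pairs" listing them.
distance_matrix <- function(seqs, labels = names(seqs),
                            model = c("K2", "JC", "p")) {
  model <- match.arg(model)
  n <- length(seqs)
  if (is.null(labels)) labels <- paste0("s", seq_len(n))
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  sat <- character(0)
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        r <- pairwise_distance(seqs[[i]], seqs[[j]], model,
                               allow_saturated = TRUE)
        m[i, j] <- m[j, i] <- r$d
        if (r$saturated) sat <- c(sat, paste(labels[i], labels[j], sep = "|"))
      }
    }
  }
  attr(m, "saturated_pairs") <- sat
  m
}

# fast pairwise P (transition) and Q (transversion) proportion matrices
# from an integer-coded alignment (A=1, C=2, G=3, T=4, NA = ambiguous),
# via indicator-matrix cross-products; transitions are |a - b| == 2
.fast_pq <- function(codes) {
  n <- nrow(codes)
  X <- lapply(1:4, function(a) {
    m <- codes == a
    m[is.na(m)] <- FALSE
    storage.mode(m) <- "double"
    m
  })
  cnt <- matrix(0, n, n)   # comparable sites
  ts <- matrix(0, n, n)
  tv <- matrix(0, n, n)
  for (a in 1:4) {
    for (b in 1:4) {
      M <- X[[a]] %*% t(X[[b]])
      cnt <- cnt + M
      if (a != b) {
        if (abs(a - b) == 2) ts <- ts + M else tv <- tv + M
      }
    }
  }
  list(P = ts / cnt, Q = tv / cnt, n = cnt)
}

# fast distance matrix (model K2/JC/p) from integer codes; NA = saturated
.fast_dist <- function(codes, labels, model = "K2") {
  pq <- .fast_pq(codes)
  P <- pq$P; Q <- pq$Q
  p <- P + Q
  d <- suppressWarnings(switch(model,
    p = p,
    JC = {
      arg <- 1 - 4 * p / 3
      ifelse(arg > 0, -3 / 4 * log(arg), NA_real_)
    },
    K2 = {
      a1 <- 1 - 2 * P - Q
      a2 <- 1 - 2 * Q
      ifelse(a1 > 0 & a2 > 0, -0.5 * log(a1) - 0.25 * log(a2), NA_real_)
    }
  ))
  diag(d) <- 0
  dimnames(d) <- list(labels, labels)
  d
}

.encode_alignment <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  codes <- matrix(match(mat, NUC), nrow = nrow(mat))
  codes
}

#' Pairwise distance matrix for an allele alignment
#'
#' @param alignment Alignment tibble with columns `allele` and `seq`
#'   (see [as_allele_alignment()]).
#' @param model Distance model: `"K2"`, `"JC"` or `"p"`.
#' @return Square numeric matrix with allele labels; saturated pairs are
#'   `NA` and listed in the `"saturated_pairs"` attribute.
#' @export
alignment_distances <- function(alignment, model = c("K2", "JC", "p")) {
  alignment <- as_allele_alignment(alignment)
  distance_matrix(alignment$seq, alignment$allele, match.arg(model))
}
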