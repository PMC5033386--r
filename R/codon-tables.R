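# Codon machinery shared by the dN/dS estimator, the Z-test, the sequence
# simulator and the genotyping stop-codon filter.
#
# Codons are indexed 1..64 in base-4 order with A=0, C=1, G=2, T=3, i.e.
# index = 16*b1 + 4*b2 + b3 + 1.

NUC <- c("A", "C", "G", "T")

# standard genetic code over the 64 base-4-ordered codons ("*" = stop)
.codon_strings <- function() {
  g <- expand.grid(b3 = NUC, b2 = NUC, b1 = NUC, stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
}

GENETIC_CODE_VEC <- local({
  code <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L",
    CTT = "L", CTC = "L", CTA = "L", CTG = "L",
    ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V",
    TCT = "S", TCC = "S", TCA = "S", TCG = "S",
    CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T",
    GCT = "A", GCC = "A", GCA = "A", GCG = "A",
    TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
    AAT = "N", AAC = "N", AAA = "K", AAG = "K",
    GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W",
    CGT = "R", CGC = "R", CGA = "R", CGG = "R",
    AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G"
  )
  unname(code[.codon_strings()])
})

CODON_STR <- .codon_strings()
STOP_IDX <- which(GENETIC_CODE_VEC == "*")
SENSE_IDX <- which(GENETIC_CODE_VEC != "*")

codon_index <- function(codon_strings) {
  m <- match(codon_strings, CODON_STR)
  m
}

# split a nucleotide string into complete codons after the frame offset;
# the 3' remainder (< 3 nt) is dropped
seq_codons <- function(seq, frame_offset = 0L) {
  s <- substring(seq, frame_offset + 1L, nchar(seq))
  n_codon <- nchar(s) %/% 3L
  if (n_codon == 0L) return(character(0))
  starts <- seq(1L, by = 3L, length.out = n_codon)
  substring(s, starts, starts + 2L)
}

#' Translate a nucleotide sequence
#'
#' Translates in the given reading frame using the standard genetic code,
#' dropping the 3' remainder that does not fill a codon. Codons containing
#' ambiguous bases translate to `X`; stops to `*`.
#'
#' @param seq Nucleotide string (A/C/G/T/N).
#' @param frame_offset Number of 5' bases to skip before the first codon
#'   (0, 1 or 2).
#' @return Amino-acid string.
#' @export
translate_seq <- function(seq, frame_offset = 0L) {
  cods <- seq_codons(seq, frame_offset)
  idx <- codon_index(cods)
  aa <- ifelse(is.na(idx), "X", GENETIC_CODE_VEC[idx])
  paste(aa, collapse = "")
}

# a stop anywhere in the translated fragment counts as internal: the
# amplicon sits inside exon 2, so no codon of the fragment may be a stop
has_internal_stop <- function(seq, frame_offset = 0L) {
  aa <- translate_seq(seq, frame_offset)
  grepl("*", aa, fixed = TRUE)
}

# neighbours of each codon: the 9 single-nucleotide mutants
.codon_neighbours <- local({
  nb <- NULL
  function() {
    if (!is.null(nb)) return(nb)
    out <- vector("list", 64L)
    for (i in 1:64) {
      cod <- strsplit(CODON_STR[i], "")[[1]]
      lst <- list()
      for (pos in 1:3) {
        for (to in setdiff(NUC, cod[pos])) {
          mut <- cod
          mut[pos] <- to
          lst[[length(lst) + 1L]] <- list(
            idx = codon_index(paste(mut, collapse = "")),
            pos = pos,
            from = cod[pos],
            to = to,
            transition = is_transition(cod[pos], to)
          )
        }
      }
      out[[i]] <- lst
    }
    nb <<- out
    nb
  }
})

is_transition <- function(from, to) {
  (from %in% c("A", "G") & to %in% c("A", "G")) |
    (from %in% c("C", "T") & to %in% c("C", "T"))
}

# Modified Nei-Gojobori potential-site counts. For each codon, each position
# contributes the weighted fraction of its three possible changes that are
# synonymous, with transitions weighted R and each transversion weighted 1
# (denominator R + 2). Changes creating a stop codon count as nonsynonymous.
# Returns a 64-vector of synonymous site counts (NA for stop codons);
# nonsynonymous sites are 3 - s.
ng_syn_sites <- function(R = 1) {
  nbrs <- .codon_neighbours()
  s <- rep(NA_real_, 64L)
  for (i in SENSE_IDX) {
    tot <- 0
    for (pos in 1:3) {
      w_syn <- 0
      w_all <- 0
      for (nb in nbrs[[i]]) {
        if (nb$pos != pos) next
        w <- if (nb$transition) R else 1
        w_all <- w_all + w
        syn <- !(nb$idx %in% STOP_IDX) &&
          GENETIC_CODE_VEC[nb$idx] == GENETIC_CODE_VEC[i]
        if (syn) w_syn <- w_syn + w
      }
      tot <- tot + w_syn / w_all
    }
    s[i] <- tot
  }
  s
}

# Pathway-averaged synonymous / nonsynonymous difference counts for every
# codon pair. For a pair differing at k positions all k! orderings of the
# single-nucleotide steps are enumerated; pathways passing through a stop
# codon are excluded (if every pathway does, all are used). Start/end stop
# codons yield NA.
ng_diff_tables <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    sd_m <- matrix(NA_real_, 64, 64)
    nd_m <- matrix(NA_real_, 64, 64)
    cod_chars <- strsplit(CODON_STR, "")
    step_class <- function(i, j) {
      # i -> j differ at exactly one position; 1 = synonymous, 0 = nonsyn
      if (GENETIC_CODE_VEC[i] == GENETIC_CODE_VEC[j]) 1L else 0L
    }
    for (i in SENSE_IDX) {
      ci <- cod_chars[[i]]
      for (j in SENSE_IDX) {
        if (j < i) next
        cj <- cod_chars[[j]]
        diffs <- which(ci != cj)
        k <- length(diffs)
        if (k == 0L) {
          sd_m[i, j] <- 0; nd_m[i, j] <- 0
          next
        }
        perms <- if (k == 1L) list(diffs) else
          if (k == 2L) list(diffs, rev(diffs)) else
            lapply(asplit(.perm3(), 1), function(o) diffs[o])
        res <- matrix(NA_real_, length(perms), 3L) # sd, nd, valid
        for (p in seq_along(perms)) {
          cur <- ci
          cur_idx <- i
          sdc <- 0L; ndc <- 0L; ok <- TRUE
          for (pos in perms[[p]]) {
            nxt <- cur
            nxt[pos] <- cj[pos]
            nxt_idx <- codon_index(paste(nxt, collapse = ""))
            if (nxt_idx %in% STOP_IDX && nxt_idx != j) ok <- FALSE
            if (GENETIC_CODE_VEC[cur_idx] == GENETIC_CODE_VEC[nxt_idx]) {
              sdc <- sdc + 1L
            } else {
              ndc <- ndc + 1L
            }
            cur <- nxt
            cur_idx <- nxt_idx
          }
          res[p, ] <- c(sdc, ndc, ok)
        }
        use <- res[, 3] == 1
        if (!any(use)) use <- rep(TRUE, nrow(res))
        sd_m[i, j] <- sd_m[j, i] <- mean(res[use, 1])
        nd_m[i, j] <- nd_m[j, i] <- mean(res[use, 2])
      }
    }
    cache <<- list(sd = sd_m, nd = nd_m)
    cache
  }
})

.perm3 <- function() {
  rbind(
    c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
    c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)
  )
}
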