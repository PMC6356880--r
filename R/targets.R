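# Seed-complementary target prediction with a simplified nearest-neighbor
# duplex-stability filter. Target sites are defined purely by perfect
# Watson-Crick complementarity to the miRNA seed (mature bases 2-8, no G:U);
# the optional energy filter extends the seed duplex while complementary
# (G:U allowed outside the seed) and sums stacking energies.

# Watson-Crick nearest-neighbor stack free energies (kcal/mol at 37 C),
# keyed by the 5'->3' dinucleotide on the miRNA strand; the paired strand is
# its complement. Standard ten-parameter RNA table expanded to all sixteen
# dinucleotides via symmetry.
.NN_WC <- c(AA = -0.93, UU = -0.93, AU = -1.10, UA = -1.33,
            AG = -2.08, CU = -2.08, CA = -2.11, UG = -2.11,
            AC = -2.24, GU = -2.24, GA = -2.35, UC = -2.35,
            CG = -2.36, GC = -3.42, CC = -3.26, GG = -3.26)

# fixed stack contribution when one or both pairs of the stack are G:U
# wobbles (simplification; documented in the methods vignette)
.NN_GU <- -0.5

#' The bundled nearest-neighbor stacking table
#'
#' @return data.frame with columns `dinucleotide` (5'->3' on the miRNA
#'   strand, Watson-Crick paired) and `dg` (kcal/mol).
#' @export
rna_nn_table <- function() {
  data.frame(dinucleotide = names(.NN_WC), dg = unname(.NN_WC),
             stringsAsFactors = FALSE)
}

#' Find perfect seed-complementary sites in a 3'UTR
#'
#' Reports every UTR position where the reverse complement of the mature's
#' seed (bases 2-8, Watson-Crick pairs only, no G:U) occurs.
#'
#' @param mature mature miRNA sequence (>= 8 nt).
#' @param utr 3'UTR sequence (5'->3').
#' @return integer vector of 1-based site start positions on the UTR (the
#'   position pairing with seed base 8).
#' @export
seed_sites <- function(mature, utr) {
  mature <- as_rna(mature)
  stopifnot(nchar(mature) >= 8L)
  utr <- as_rna(utr)
  motif <- revcomp_rna(substr(mature, 2L, 8L))
  if (grepl("N", motif, fixed = TRUE)) return(integer(0))
  .find_all_fixed(motif, utr)[[1]]
}

# can mature base a pair with utr base b (WC or GU)?
.pairs_wc_gu <- function(a, b) {
  (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G") |
    (a == "G" & b == "U") | (a == "U" & b == "G")
}
.pairs_wc <- function(a, b) {
  (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
}

#' Duplex free energy of a seed site with complementary extension
#'
#' Starting from the seed duplex (mature bases 2-8 paired to the site), the
#' duplex is extended base by base in both directions while Watson-Crick or
#' G:U pairing holds; the first non-pairing position terminates extension
#' (no internal loops or bulges). The energy is the sum of nearest-neighbor
#' stacking terms over the paired run; more negative is more stable.
#'
#' @param mature mature miRNA sequence.
#' @param utr 3'UTR sequence.
#' @param site a site start from [seed_sites()].
#' @return duplex free energy in kcal/mol.
#' @export
duplex_energy <- function(mature, utr, site) {
  mature <- as_rna(mature); utr <- as_rna(utr)
  mb <- strsplit(mature, "")[[1]]
  ub <- strsplit(utr, "")[[1]]
  lm <- length(mb); lu <- length(ub)
  # mature base k (1-based) pairs utr position site + 8 - k
  partner <- function(k) site + 8L - k
  lo <- 2L; hi <- 8L
  while (lo > 1L && partner(lo - 1L) <= lu &&
         .pairs_wc_gu(mb[lo - 1L], ub[partner(lo - 1L)])) lo <- lo - 1L
  while (hi < lm && partner(hi + 1L) >= 1L &&
         .pairs_wc_gu(mb[hi + 1L], ub[partner(hi + 1L)])) hi <- hi + 1L
  if (hi == lo) return(0)
  e <- 0
  for (k in lo:(hi - 1L)) {
    wc <- .pairs_wc(mb[k], ub[partner(k)]) &&
      .pairs_wc(mb[k + 1L], ub[partner(k + 1L)])
    e <- e + if (wc) .NN_WC[[paste0(mb[k], mb[k + 1L])]] else .NN_GU
  }
  e
}

#' Predict target transcripts for a set of mature miRNAs
#'
#' A transcript is a predicted target of a mature when its 3'UTR carries at
#' least one perfect seed-complementary site that (optionally) passes the
#' duplex stability threshold.
#'
#' @param matures named character vector of mature sequences.
#' @param utrs named character vector of 3'UTR sequences.
#' @param energy_threshold maximum (most positive) admissible duplex energy
#'   in kcal/mol.
#' @param use_energy apply the stability filter?
#' @return named list mapping each mature id to a character vector of target
#'   transcript ids, with the UTR universe attached as attribute
#'   `"universe"`.
#' @export
predict_targets <- function(matures, utrs, energy_threshold = -18,
                            use_energy = TRUE) {
  stopifnot(!is.null(names(matures)))
  if (!length(utrs)) {
    out <- lapply(matures, function(m) character(0))
    attr(out, "universe") <- character(0)
    return(out)
  }
  stopifnot(!is.null(names(utrs)))
  utrs <- as_rna(utrs)
  out <- lapply(as_rna(matures), function(m) {
    hit <- vapply(seq_along(utrs), function(j) {
      sites <- seed_sites(m, utrs[[j]])
      if (!length(sites)) return(FALSE)
      if (!use_energy) return(TRUE)
      any(vapply(sites, function(s) duplex_energy(m, utrs[[j]], s),
                 numeric(1)) <= energy_threshold)
    }, logical(1))
    names(utrs)[hit]
  })
  names(out) <- names(matures)
  attr(out, "universe") <- sort(names(utrs))
  out
}

#' Compare canonical and variant target repertoires
#'
#' Transcript-level set comparison: a transcript counts once regardless of
#' site multiplicity or how many matures hit it.
#'
#' @param canonical,variant [predict_targets()] mappings over the same UTR
#'   universe.
#' @return list of class `target_set_comparison`: `canonical_total`,
#'   `shared`, `canonical_only`, `variant_only`, and `percent_added`
#'   (variant-only transcripts as a percentage of the canonical total).
#' @export
compare_target_sets <- function(canonical, variant) {
  ucan <- attr(canonical, "universe"); uvar <- attr(variant, "universe")
  if (!is.null(ucan) && !is.null(uvar) && !identical(ucan, uvar)) {
    stop("target mappings were computed over different UTR universes")
  }
  cset <- unique(unlist(canonical, use.names = FALSE))
  vset <- unique(unlist(variant, use.names = FALSE))
  shared <- intersect(cset, vset)
  structure(list(canonical_total = length(cset),
                 shared = length(shared),
                 canonical_only = length(setdiff(cset, vset)),
                 variant_only = length(setdiff(vset, cset)),
                 percent_added = if (length(cset))
                   100 * length(setdiff(vset, cset)) / length(cset)
                 else NA_real_),
            class = "target_set_comparison")
}
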