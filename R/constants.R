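#' The 20 standard amino-acid one-letter codes
#'
#' @return character vector of the 20 standard residues, alphabetical.
#' @export
aaAlphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' All 400 ordered dipeptide names in grid order
#'
#' First letter major, alphabetical within: AA, AC, ..., AY, CA, ..., YY.
#'
#' @return character vector of length 400.
#' @export
dipeptideNames <- function() {
  aa <- aaAlphabet()
  as.vector(t(outer(aa, aa, paste0)))
}

#' Reference dipeptide subsets discriminating aaRS classes
#'
#' The fixed, published subsets of dipeptides whose composition separates
#' (stage 1) aaRS from non-aaRS proteins, and (stage 2) class-1 from
#' class-2 aaRSs. These are the default composition features of the two
#' hybrid pipelines; \code{\link{rankFeatures}} reproduces the selection
#' procedure on new data.
#'
#' @param stage \code{"stage1"} (18 dipeptides, aaRS vs non-aaRS) or
#'   \code{"stage2"} (14 dipeptides, class-1 vs class-2).
#' @return character vector of dipeptide names.
#' @export
selectedDipeptides <- function(stage = c("stage1", "stage2")) {
  stage <- match.arg(stage)
  if (stage == "stage1")
    c("CL", "DR", "FY", "GM", "GR", "GS", "IN", "MV", "ND",
      "PL", "QI", "QR", "RD", "RF", "ST", "WF", "YD", "YV")
  else
    c("AY", "DP", "DW", "EN", "EV", "GH", "IG", "KM",
      "PW", "QW", "SG", "WD", "YA", "YV")
}

#' PROSITE domains used as binary hybrid features
#'
#' Stage 1 uses the four domains most discriminative for aaRS vs non-aaRS
#' (PS50862 AA_TRNA_LIGASE_II, PS00178 AA_TRNA_LIGASE_I, PS50860
#' AA_TRNA_LIGASE_II_ALA, PS50861 AA_TRNA_LIGASE_II_GLYAB); stage 2 adds
#' the S4 RNA-binding domain PS50889 found in tyrosyl-tRNA synthetases.
#'
#' @param stage \code{"stage1"} (4 accessions) or \code{"stage2"} (5).
#' @return ordered character vector of accessions.
#' @export
prositeDomains <- function(stage = c("stage1", "stage2")) {
  stage <- match.arg(stage)
  base <- c("PS50862", "PS00178", "PS50860", "PS50861")
  if (stage == "stage1") base else c(base, "PS50889")
}

#' Class-preferred PROSITE domains
#'
#' Among the stage-2 domains, PS00178 (which contains the HIGH signature)
#' and PS50889 are preferred in class-1 aaRSs, while PS50862, PS50860 and
#' PS50861 are preferred in class-2.
#'
#' @return named list with elements \code{class1} and \code{class2}.
#' @export
classPreferredDomains <- function() {
  list(class1 = c("PS00178", "PS50889"),
       class2 = c("PS50862", "PS50860", "PS50861"))
}

#' Synthetic motif strings standing in for domain signatures
#'
#' Exact peptide strings used by the synthetic generator so that planted
#' sequence content and emitted domain-hit tables agree, and so the
#' built-in pattern matcher can recover pattern-type hits. PS00178 carries
#' the genuine class-1 HIGH signature core; the profile-type domains
#' (detected in real data by weight-matrix scanning, which this package
#' does not re-implement) are given arbitrary synthetic stand-in motifs.
#'
#' @return named character vector, one motif per accession.
#' @export
syntheticDomainMotifs <- function() {
  c(PS00178 = "HIGH",
    PS50862 = "FRAEGY",
    PS50860 = "WDNMGA",
    PS50861 = "YPMCGE",
    PS50889 = "RKDLNQ")
}

#' Background residue frequencies for the sequence generator
#'
#' @param type \code{"uniform"} (1/20 each) or \code{"swissprot"}, a
#'   bundled table of approximate Swiss-Prot-wide residue frequencies.
#' @return named numeric vector over \code{\link{aaAlphabet}} summing to 1.
#' @export
backgroundFrequencies <- function(type = c("uniform", "swissprot")) {
  type <- match.arg(type)
  aa <- aaAlphabet()
  if (type == "uniform")
    return(stats::setNames(rep(1 / 20, 20), aa))
  ## approximate UniProtKB/Swiss-Prot residue percentages
  p <- c(A = 8.25, C = 1.38, D = 5.46, E = 6.72, F = 3.86, G = 7.07,
         H = 2.27, I = 5.91, K = 5.80, L = 9.65, M = 2.41, N = 4.06,
         P = 4.74, Q = 3.93, R = 5.53, S = 6.64, T = 5.35, V = 6.86,
         W = 1.10, Y = 2.92)[aa]
  p / sum(p)
}

## run expr under a temporary RNG state seeded with `seed`, restoring the
## caller's stream afterwards
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
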