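## Seed-anchored miRNA target-site scanner (miRanda-style) with
## TargetScan-style seed classes and a simplified nearest-neighbor
## duplex-energy estimate.

## RNA/RNA Watson-Crick nearest-neighbor stacking terms (kcal/mol),
## indexed by the 5'->3' dinucleotide step on the miRNA strand.
.STACK_WC <- c(
  AA = -0.93, AU = -1.10, AC = -2.24, AG = -2.08,
  UA = -1.33, UU = -0.93, UC = -2.35, UG = -2.11,
  CA = -2.11, CU = -2.08, CC = -3.26, CG = -2.36,
  GA = -2.35, GU = -2.24, GC = -3.42, GG = -3.26)

#' Scanner parameters
#'
#' Defaults mirror miRanda's published thresholds: minimum alignment
#' score 140 and maximum duplex energy -1.0 kcal/mol. Alignment scoring:
#' Watson-Crick pair +5, G:U wobble +1 (disallowed inside the seed
#' unless `gu_in_seed`), mismatch -3, gap open -9, gap extend -4, with
#' contributions from miRNA positions 2-8 doubled.
#'
#' @param score_min Minimum alignment score for a reported site.
#' @param energy_max Maximum (most positive) duplex energy in kcal/mol.
#' @param gu_in_seed Allow G:U pairs to score as wobbles at miRNA
#'   positions 2-8 (default `FALSE`: they score as mismatches there).
#' @param match,gu,mismatch,gap_open,gap_extend Alignment scores.
#' @param gu_stack Stacking term used when a step involves a G:U pair.
#' @param stack_table Named stacking-term table (see source); swappable.
#' @param max_gap_span Extra target positions allowed for bulges in the
#'   3' extension.
#' @return A list of scanner parameters.
#' @export
scanParams <- function(score_min = 140, energy_max = -1.0,
                       gu_in_seed = FALSE, match = 5, gu = 1,
                       mismatch = -3, gap_open = -9, gap_extend = -4,
                       gu_stack = -0.5, stack_table = .STACK_WC,
                       max_gap_span = 6L) {
  list(score_min = score_min, energy_max = energy_max,
       gu_in_seed = gu_in_seed, match = match, gu = gu,
       mismatch = mismatch, gap_open = gap_open, gap_extend = gap_extend,
       gu_stack = gu_stack, stack_table = stack_table,
       max_gap_span = as.integer(max_gap_span))
}

.isWC <- function(a, b) .RNA_COMP[a] == b
.isGU <- function(a, b) (a == "G" & b == "U") | (a == "U" & b == "G")

## score of pairing miRNA base a (at position pos) against target base b
.pairScore <- function(a, b, pos, params) {
  w <- if (pos >= 2L && pos <= 8L) 2 else 1
  if (is.na(.RNA_COMP[a]) || !b %in% c("A", "C", "G", "U"))
    return(w * params$mismatch)
  if (.isWC(a, b)) return(w * params$match)
  if (.isGU(a, b)) {
    if (pos >= 2L && pos <= 8L && !params$gu_in_seed)
      return(w * params$mismatch)
    return(w * params$gu)
  }
  w * params$mismatch
}

#' Seed-complementary anchor positions
#'
#' Every target window (1-based start on the target, 5'->3') whose six
#' bases are the exact Watson-Crick reverse complement of miRNA
#' positions 2-7. This is phase 1 of [scanMirnaSites()].
#'
#' @param mirna_seq Mature miRNA (RNA or DNA alphabet).
#' @param target_seq Target sequence.
#' @return Integer vector of anchor start positions (possibly empty).
#' @export
seedAnchors <- function(mirna_seq, target_seq) {
  m <- .toRNA(mirna_seq); tg <- .toRNA(target_seq)
  if (nchar(m) < 8L) stop("miRNA shorter than 8 nt")
  if (nchar(tg) < 6L) return(integer(0))
  pat <- .revcompRNA(substr(m, 2L, 7L))
  .anchorHits(pat, tg)
}

## all (overlapping) occurrences of a literal pattern via a zero-width
## lookahead
.anchorHits <- function(pat, seq) {
  hits <- gregexpr(paste0("(?=", pat, ")"), seq, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) return(integer(0))
  as.integer(hits)
}

## affine-gap extension of the duplex over miRNA positions 8..L against
## the target region 5' of the anchor; anchored at (pos 8, s-1), may end
## anywhere (local), never negative
.extendScore <- function(m, tg, s, params) {
  L <- length(m)
  n1 <- L - 7L
  n2 <- min(s - 1L, n1 + params$max_gap_span)
  if (n1 <= 0L || n2 <= 0L) return(list(score = 0, left = s))
  mi <- m[8:L]
  tj <- tg[(s - 1L):(s - n2)]
  NEG <- -1e9
  M <- matrix(NEG, n1 + 1L, n2 + 1L)
  Ix <- matrix(NEG, n1 + 1L, n2 + 1L)  # gap in target
  Iy <- matrix(NEG, n1 + 1L, n2 + 1L)  # gap in miRNA
  M[1L, 1L] <- 0
  for (i in seq_len(n1))
    Ix[i + 1L, 1L] <- params$gap_open + (i - 1L) * params$gap_extend
  for (j in seq_len(n2))
    Iy[1L, j + 1L] <- params$gap_open + (j - 1L) * params$gap_extend
  best <- 0; bestj <- 0L
  for (i in seq_len(n1)) {
    ps_row <- vapply(tj, function(b)
      .pairScore(mi[i], b, pos = 7L + i, params), numeric(1))
    for (j in seq_len(n2)) {
      prev <- max(M[i, j], Ix[i, j], Iy[i, j])
      M[i + 1L, j + 1L] <- ps_row[j] + prev
      Ix[i + 1L, j + 1L] <- max(M[i, j + 1L] + params$gap_open,
                                Ix[i, j + 1L] + params$gap_extend)
      Iy[i + 1L, j + 1L] <- max(M[i + 1L, j] + params$gap_open,
                                Iy[i + 1L, j] + params$gap_extend)
      if (M[i + 1L, j + 1L] > best) {
        best <- M[i + 1L, j + 1L]
        bestj <- j
      }
    }
  }
  list(score = best, left = s - bestj)
}

## simplified duplex energy: nearest-neighbor stack sum over consecutive
## paired positions of the ungapped registration around the anchor
.duplexEnergy <- function(m, tg, s, params) {
  L <- length(m)
  tlen <- length(tg)
  paired <- logical(L); guflag <- logical(L)
  for (k in seq_len(L)) {
    u <- s + 7L - k  # target index opposite miRNA position k
    if (u >= 1L && u <= tlen) {
      paired[k] <- .isWC(m[k], tg[u]) || .isGU(m[k], tg[u])
      guflag[k] <- .isGU(m[k], tg[u])
    }
  }
  e <- 0
  for (k in seq_len(L - 1L)) {
    if (paired[k] && paired[k + 1L]) {
      step <- paste0(m[k], m[k + 1L])
      e <- e + if (guflag[k] || guflag[k + 1L]) params$gu_stack
      else params$stack_table[[step]]
    }
  }
  e
}

#' Scan a target sequence for miRNA binding sites
#'
#' Three phases: (1) anchor search — every target window exactly
#' Watson-Crick complementary to miRNA seed positions 2-7
#' ([seedAnchors()]); (2) scored extension of the duplex over miRNA
#' positions 8 to the 3' end by a local affine-gap alignment (G:U
#' allowed outside the seed), with position 1 paired ungapped;
#' (3) duplex energy estimated as a nearest-neighbor stacking sum over
#' the ungapped registration. Sites are reported when
#' `align_score >= score_min` and `energy <= energy_max`; overlapping
#' sites are resolved by keeping the higher score (ties: leftmost).
#'
#' @param mirna_seq Mature miRNA, 18-26 nt (RNA or DNA alphabet).
#' @param target_seq Target sequence, >= 8 nt.
#' @param params Parameters from [scanParams()].
#' @param mirna,target_id Labels carried into the output.
#' @return Data.frame with `mirna`, `target_id`, `target_start`,
#'   `target_end` (1-based inclusive), `align_score`,
#'   `energy_kcal_mol`, `seed` (TargetScan-style class from
#'   [seedClass()]) and `seed_start` (anchor position).
#' @examples
#' mir <- "UGGAAUGUAAAGAAGUAUGUAU"
#' target <- paste0("GGGGGG",
#'   as.character(Biostrings::reverseComplement(
#'     Biostrings::DNAString(gsub("U", "T", mir)))), "GGGGGG")
#' scanMirnaSites(mir, target)
#' @export
scanMirnaSites <- function(mirna_seq, target_seq, params = scanParams(),
                           mirna = "miRNA", target_id = "target") {
  mseq <- .toRNA(mirna_seq); tseq <- .toRNA(target_seq)
  .checkAlphabet(setNames(mseq, mirna), extra = "", what = "miRNA")
  .checkAlphabet(setNames(tseq, target_id), extra = "N", what = "target")
  if (nchar(mseq) < 18L || nchar(mseq) > 26L)
    stop("miRNA length outside [18, 26]")
  if (nchar(tseq) < 8L) stop("target shorter than 8 nt")
  empty <- data.frame(mirna = character(), target_id = character(),
                      target_start = integer(), target_end = integer(),
                      align_score = numeric(), energy_kcal_mol = numeric(),
                      seed = character(), seed_start = integer(),
                      stringsAsFactors = FALSE)
  anchors <- seedAnchors(mseq, tseq)
  if (!length(anchors)) return(empty)
  m <- strsplit(mseq, "")[[1L]]
  tg <- strsplit(tseq, "")[[1L]]
  tlen <- length(tg)
  rows <- lapply(anchors, function(s) {
    seed_score <- 6 * 2 * params$match  # positions 2-7, doubled
    p1 <- 0; endpos <- s + 5L
    if (s + 6L <= tlen) {
      sc1 <- .pairScore(m[1L], tg[s + 6L], pos = 1L, params)
      if (sc1 > 0) { p1 <- sc1; endpos <- s + 6L }
    }
    ext <- .extendScore(m, tg, s, params)
    score <- seed_score + p1 + ext$score
    energy <- .duplexEnergy(m, tg, s, params)
    data.frame(mirna = mirna, target_id = target_id,
               target_start = as.integer(min(ext$left, s)),
               target_end = as.integer(endpos),
               align_score = score, energy_kcal_mol = energy,
               seed = seedClass(mseq, tseq, s),
               seed_start = as.integer(s), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$align_score >= params$score_min &
               out$energy_kcal_mol <= params$energy_max, , drop = FALSE]
  if (!nrow(out)) return(empty)
  ## overlap resolution: higher score wins, ties to the leftmost site
  out <- out[order(-out$align_score, out$target_start), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    if (i < nrow(out)) {
      later <- (i + 1L):nrow(out)
      ov <- out$target_start[later] <= out$target_end[i] &
        out$target_end[later] >= out$target_start[i]
      keep[later][ov] <- FALSE
    }
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$target_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' TargetScan-style canonical seed class of a site
#'
#' Classes: `8mer` (Watson-Crick match to miRNA positions 2-8 plus an A
#' on the target opposite position 1), `7mer-m8` (WC 2-8), `7mer-A1`
#' (WC 2-7 plus the A), `6mer` (WC 2-7 only), `none` otherwise. A G:U
#' pair inside the seed disqualifies all canonical classes.
#'
#' @param mirna_seq Mature miRNA.
#' @param target_seq Target sequence.
#' @param seed_start 1-based target position of the 6-mer opposite miRNA
#'   positions 2-7 (the `seed_start` column of [scanMirnaSites()]).
#' @return One of `"8mer"`, `"7mer-m8"`, `"7mer-A1"`, `"6mer"`,
#'   `"none"`.
#' @export
seedClass <- function(mirna_seq, target_seq, seed_start) {
  m <- strsplit(.toRNA(mirna_seq), "")[[1L]]
  tg <- strsplit(.toRNA(target_seq), "")[[1L]]
  s <- as.integer(seed_start)
  if (s < 1L || s + 5L > length(tg)) stop("invalid seed_start")
  wc27 <- all(vapply(2:7, function(k)
    isTRUE(.isWC(m[k], tg[s + 7L - k])), logical(1)))
  if (!wc27) return("none")
  m8 <- s - 1L >= 1L && length(m) >= 8L && isTRUE(.isWC(m[8L], tg[s - 1L]))
  a1 <- s + 6L <= length(tg) && tg[s + 6L] == "A"
  if (m8 && a1) return("8mer")
  if (m8) return("7mer-m8")
  if (a1) return("7mer-A1")
  "6mer"
}

#' Scan many miRNA/target pairs into one site table
#'
#' @param mirnas Named character vector of mature sequences.
#' @param targets Named character vector of target sequences.
#' @param params [scanParams()].
#' @return Row-bound site table over all pairs (possibly empty).
#' @export
scanSiteTable <- function(mirnas, targets, params = scanParams()) {
  out <- list()
  for (mn in names(mirnas)) {
    for (tn in names(targets)) {
      s <- scanMirnaSites(mirnas[[mn]], targets[[tn]], params,
                          mirna = mn, target_id = tn)
      if (nrow(s)) out[[length(out) + 1L]] <- s
    }
  }
  if (!length(out))
    return(scanMirnaSites("UGAGGUAGUAGGUUGUAUAGUU", "GGGGGGGG",
                          params)[0L, ])
  do.call(rbind, out)
}
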