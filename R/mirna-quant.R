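## Assignment of small-RNA tags to known mature miRNAs and the
## descriptive summaries reported for small-RNA libraries.

#' Build validated mature miRNA records
#'
#' @param name Character vector of miRNA names.
#' @param mature_seq Mature sequences (RNA or DNA alphabet; stored as
#'   RNA), lengths 18-26 nt.
#' @param precursor_id Optional precursor ids.
#' @param precursor_seq Optional precursor sequences; when given, the
#'   mature must be a substring of its precursor.
#' @return Data.frame with columns `name`, `mature_seq`, `precursor_id`,
#'   `precursor_seq`.
#' @export
mirnaRecords <- function(name, mature_seq, precursor_id = NA_character_,
                         precursor_seq = NA_character_) {
  mature_seq <- .toRNA(mature_seq)
  if (anyDuplicated(name)) stop("duplicate miRNA name(s)")
  len <- nchar(mature_seq)
  if (any(len < 18L | len > 26L))
    stop("mature sequence length outside [18, 26] for: ",
         paste(name[len < 18L | len > 26L], collapse = ", "))
  .checkAlphabet(setNames(mature_seq, name), extra = "", what = "mature miRNA")
  df <- data.frame(name = name, mature_seq = mature_seq,
                   precursor_id = precursor_id,
                   precursor_seq = .toRNA(precursor_seq),
                   stringsAsFactors = FALSE)
  bad <- !is.na(df$precursor_seq) &
    !mapply(grepl, df$mature_seq, df$precursor_seq, MoreArgs = list(fixed = TRUE))
  if (any(bad))
    stop("mature not contained in precursor for: ",
         paste(df$name[bad], collapse = ", "))
  df
}

## build sequence -> miRNA-name lookup; on collisions the
## lexicographically smallest name wins and the entry is flagged
.seqLookup <- function(seqs, names) {
  o <- order(seqs, names)
  seqs <- seqs[o]; names <- names[o]
  first <- !duplicated(seqs)
  tie <- seqs %in% seqs[duplicated(seqs)]
  list(map = setNames(names[first], seqs[first]),
       tied = unique(seqs[tie]))
}

#' Assign small-RNA tags to known mature miRNAs
#'
#' Exact sequence matches are assigned first; remaining tags matching a
#' mature trimmed by up to `tolerance` nt at the 3' end, or extended by
#' up to `tolerance` nt of its precursor context, are assigned as
#' 3'-isomiRs. Each tag goes to at most one miRNA; ties are broken by
#' the lexicographically smallest name and flagged. Tags outside
#' 18-30 nt are rejected with a reason and excluded from per-miRNA
#' counts.
#'
#' @param tags Data.frame with columns `seq` and `count` (one small-RNA
#'   library).
#' @param records miRNA records from [mirnaRecords()].
#' @param tolerance Maximum 3' trim/extension in nt (default 2; 0 gives
#'   exact-only matching).
#' @return List with `assignments` (tag, count, assigned_mirna,
#'   match_type in `{exact, iso_3p_trim, unassigned, rejected_length}`,
#'   `tied` flag) and `counts` (named per-miRNA totals). Total input
#'   counts are conserved across assigned + unassigned + rejected.
#' @export
assignTags <- function(tags, records, tolerance = 2L) {
  stopifnot(is.data.frame(tags), all(c("seq", "count") %in% colnames(tags)))
  if (tolerance < 0L) stop("tolerance must be >= 0")
  tseq <- .toRNA(tags$seq)
  cnt <- as.numeric(tags$count)
  if (any(cnt < 1)) stop("tag counts must be >= 1")
  mat <- setNames(records$mature_seq, records$name)

  exact <- .seqLookup(unname(mat), names(mat))
  vs <- character(0); vn <- character(0)
  if (tolerance > 0L) {
    for (k in seq_len(tolerance)) {
      keep <- nchar(mat) - k >= 1L
      vs <- c(vs, substr(mat[keep], 1L, nchar(mat[keep]) - k))
      vn <- c(vn, names(mat)[keep])
      has_prec <- !is.na(records$precursor_seq)
      for (i in which(has_prec)) {
        pos <- regexpr(records$mature_seq[i], records$precursor_seq[i],
                       fixed = TRUE)
        endp <- pos + nchar(records$mature_seq[i]) - 1L + k
        if (pos > 0L && endp <= nchar(records$precursor_seq[i])) {
          vs <- c(vs, substr(records$precursor_seq[i], pos, endp))
          vn <- c(vn, records$name[i])
        }
      }
    }
  }
  ## exact sequences shadow isomiR variants
  keep <- !vs %in% names(exact$map)
  iso <- .seqLookup(vs[keep], vn[keep])

  len <- nchar(tseq)
  rejected <- len < 18L | len > 30L
  hit_exact <- !rejected & tseq %in% names(exact$map)
  hit_iso <- !rejected & !hit_exact & tseq %in% names(iso$map)
  assigned <- rep(NA_character_, length(tseq))
  assigned[hit_exact] <- exact$map[tseq[hit_exact]]
  assigned[hit_iso] <- iso$map[tseq[hit_iso]]
  type <- rep("unassigned", length(tseq))
  type[hit_exact] <- "exact"
  type[hit_iso] <- "iso_3p_trim"
  type[rejected] <- "rejected_length"
  tied <- (hit_exact & tseq %in% exact$tied) | (hit_iso & tseq %in% iso$tied)

  counts <- setNames(numeric(nrow(records)), records$name)
  ok <- !is.na(assigned)
  if (any(ok)) {
    agg <- tapply(cnt[ok], assigned[ok], sum)
    counts[names(agg)] <- agg
  }
  list(assignments = data.frame(tag = tseq, count = cnt,
                                assigned_mirna = assigned,
                                match_type = type, tied = tied,
                                stringsAsFactors = FALSE),
       counts = counts)
}

#' Tag length distribution
#'
#' @param tags Data.frame with `seq` and `count`.
#' @return Named numeric vector mapping tag length to total count (sums
#'   to the total input count).
#' @export
lengthDistribution <- function(tags) {
  if (!nrow(tags)) return(setNames(numeric(0), character(0)))
  agg <- tapply(as.numeric(tags$count), nchar(tags$seq), sum)
  setNames(as.numeric(agg), names(agg))
}

#' First-position base bias by tag length
#'
#' @param tags Data.frame with `seq` (or `tag`, as in the assignment
#'   table of [assignTags()]) and `count`.
#' @return Matrix with one row per observed length and columns
#'   `A, C, G, U`; rows sum to 1.
#' @export
firstBaseBias <- function(tags) {
  if (!nrow(tags)) stop("no tags")
  seqs <- if (!is.null(tags$seq)) tags$seq else tags$tag
  if (is.null(seqs)) stop("tags need a 'seq' or 'tag' column")
  first <- substr(.toRNA(seqs), 1L, 1L)
  len <- nchar(seqs)
  bases <- c("A", "C", "G", "U")
  tab <- tapply(as.numeric(tags$count),
                list(factor(len), factor(first, levels = bases)), sum)
  tab[is.na(tab)] <- 0
  sweep(tab, 1L, rowSums(tab), "/")
}
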