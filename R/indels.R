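# Simple indel coding: each distinct maximal gap run (same start and end
# across sequences) becomes one binary character, mirroring the practice of
# recoding alignment gaps as single polymorphic characters before computing
# sequence-based diversity indices.

#' Code alignment gaps as binary indel characters
#'
#' Scans each sequence for maximal runs of `-` and emits one binary column
#' per distinct (start, end) gap event; a sequence scores 1 where it
#' carries the gap. Gap events shared by every sequence are monomorphic and
#' are dropped (they carry no information for diversity indices).
#'
#' @param alignment named character vector of equal-length gapped
#'   sequences.
#' @return binary matrix (sequences x indel characters); zero columns when
#'   no polymorphic gap event exists. Column names are `indel_<start>_<end>`.
#' @export
code_indels <- function(alignment) {
  if (length(alignment) == 0L) stop("code_indels: empty alignment")
  lens <- nchar(alignment)
  if (length(unique(lens)) > 1L)
    stop("code_indels: sequences are not aligned (unequal lengths)")
  events <- lapply(alignment, function(s) {
    m <- gregexpr("-+", s)[[1]]
    if (m[1] == -1L) return(character(0))
    start <- as.integer(m)
    end <- start + attr(m, "match.length") - 1L
    paste(start, end, sep = "_")
  })
  all_events <- sort(unique(unlist(events)))
  keep <- vapply(all_events,
                 function(ev) !all(vapply(events, function(e) ev %in% e,
                                          logical(1))),
                 logical(1))
  all_events <- all_events[keep]
  out <- matrix(0L, nrow = length(alignment), ncol = length(all_events),
                dimnames = list(names(alignment),
                                if (length(all_events))
                                  paste0("indel_", all_events) else NULL))
  for (i in seq_along(alignment))
    out[i, paste0("indel_", intersect(events[[i]], all_events),
                  recycle0 = TRUE)] <- 1L
  # order columns by numeric (start, end)
  if (ncol(out) > 1L) {
    se <- do.call(rbind, lapply(strsplit(sub("^indel_", "", colnames(out)),
                                         "_"), as.integer))
    out <- out[, order(se[, 1], se[, 2]), drop = FALSE]
  }
  out
}

#' Bundle aligned cpDNA sequences into haplotype data
#'
#' Codes indels via [code_indels()] and assigns haplotype labels:
#' individuals share a haplotype iff their aligned sequence and their
#' coded-indel row are both identical.
#'
#' @param alignment named character vector of equal-length sequences
#'   (individual ids as names).
#' @param pop_of named character vector mapping individual id -> pop_id.
#' @return list of class `haplotype_data` with `alignment`,
#'   `indel_characters`, `haplotype_id`, `pop_of`, `individuals`.
#' @export
haplotype_data <- function(alignment, pop_of) {
  if (is.null(names(alignment)))
    stop("haplotype_data: alignment must have individual ids as names")
  miss <- setdiff(names(alignment), names(pop_of))
  if (length(miss))
    stop("haplotype_data: individuals without population mapping: ",
         paste(miss, collapse = ", "))
  ind <- code_indels(alignment)
  key <- paste(alignment, apply(ind, 1L, paste, collapse = ""))
  hap <- stats::setNames(paste0("H", as.integer(factor(key,
                                                       levels = unique(key)))),
                         names(alignment))
  structure(list(individuals = names(alignment),
                 alignment = alignment,
                 indel_characters = ind,
                 haplotype_id = hap,
                 pop_of = pop_of[names(alignment)]),
            class = "haplotype_data")
}
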