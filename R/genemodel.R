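#' Gene model and signal interval tibbles
#'
#' Gene models and signal intervals are tibbles with columns `seqid`,
#' `start`, `end` (1-based, closed, `start <= end`), `strand` (`"+"` or
#' `"-"`), an id column (`gene` or `peak`), and for gene models a `source`
#' tag in `annotated`/`extended`/`novel`. The gap between two intervals is
#' `start2 - end1 - 1` (0 when abutting).
#'
#' @param x a data frame.
#' @param id_col name of the id column.
#' @return The validated tibble.
#' @keywords internal
validate_intervals <- function(x, id_col = "gene") {
  x <- tibble::as_tibble(x)
  need <- c("seqid", "start", "end", "strand", id_col)
  if (!all(need %in% names(x))) {
    stop("missing columns: ", paste(setdiff(need, names(x)), collapse = ", "),
         call. = FALSE)
  }
  if (!all(x$strand %in% c("+", "-"))) stop("malformed strand", call. = FALSE)
  if (any(x$start < 1 | x$end < x$start)) {
    stop("intervals must satisfy 1 <= start <= end", call. = FALSE)
  }
  x
}

interval_gap <- function(end1, start2) pmax(start2 - end1 - 1, 0)

#' Extend gene 3' ends toward downstream signal intervals
#'
#' 3'-biased protocols (MARS-seq) place most reads downstream of annotated
#' gene ends when 3' UTRs are under-annotated. For each gene, this finds
#' the nearest same-strand signal peak downstream of its 3' end with a gap
#' of at most `max_gap` (default 2,000 bp) that does not overlap any other
#' gene on the same strand (the downstream gene), and extends the gene's 3'
#' end to the peak's far edge. Genes without a qualifying peak are
#' unchanged. Extension only ever advances the 3' end.
#'
#' @param genes gene-model tibble (see [validate_intervals()]).
#' @param peaks signal-interval tibble with id column `peak`.
#' @param max_gap maximum gap in bp between gene 3' end and peak near edge
#'   (default 2000); gap is `0` for abutting or overlapping intervals.
#' @param block_any_strand when `TRUE`, a peak overlapping a downstream
#'   gene on either strand disqualifies it (default `FALSE`: same strand
#'   only).
#' @return Gene-model tibble sorted by (`seqid`, `start`), `source` set to
#'   `"extended"` where changed; attribute `"extension_report"` is a tibble
#'   (`gene`, `peak`, `gap`, `old_end3`, `new_end3`).
#' @export
extend_genes <- function(genes, peaks, max_gap = 2000,
                         block_any_strand = FALSE) {
  genes <- validate_intervals(genes, "gene")
  peaks <- validate_intervals(peaks, "peak")
  if (!"source" %in% names(genes)) genes$source <- "annotated"
  report <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    others <- genes[-i, , drop = FALSE]
    cand <- peaks[peaks$seqid == g$seqid & peaks$strand == g$strand, ,
                  drop = FALSE]
    if (!nrow(cand)) next
    if (g$strand == "+") {
      downstream <- cand$end > g$end
      gap <- interval_gap(g$end, cand$start)
    } else {
      downstream <- cand$start < g$start
      gap <- interval_gap(cand$end, g$start)
    }
    ok <- downstream & gap <= max_gap
    if (any(ok)) {
      blockers <- others[others$seqid == g$seqid &
                           (block_any_strand | others$strand == g$strand), ,
                         drop = FALSE]
      if (nrow(blockers)) {
        overlaps_gene <- vapply(which(ok), function(j) {
          any(cand$start[j] <= blockers$end & cand$end[j] >= blockers$start)
        }, logical(1))
        ok[which(ok)[overlaps_gene]] <- FALSE
      }
    }
    if (!any(ok)) next
    best <- which(ok)[which.min(gap[ok])]
    if (g$strand == "+") {
      new_end <- max(g$end, cand$end[best])
      if (new_end > g$end) {
        report[[length(report) + 1]] <- tibble::tibble(
          gene = g$gene, peak = cand$peak[best], gap = gap[best],
          old_end3 = g$end, new_end3 = new_end)
        genes$end[i] <- new_end
        genes$source[i] <- "extended"
      }
    } else {
      new_start <- min(g$start, cand$start[best])
      if (new_start < g$start) {
        report[[length(report) + 1]] <- tibble::tibble(
          gene = g$gene, peak = cand$peak[best], gap = gap[best],
          old_end3 = g$start, new_end3 = new_start)
        genes$start[i] <- new_start
        genes$source[i] <- "extended"
      }
    }
  }
  out <- dplyr::arrange(genes, .data$seqid, .data$start, .data$end)
  attr(out, "extension_report") <- if (length(report)) {
    dplyr::bind_rows(report)
  } else {
    tibble::tibble(gene = character(), peak = character(), gap = numeric(),
                   old_end3 = numeric(), new_end3 = numeric())
  }
  out
}

#' Materialize orphan signal intervals as novel gene models
#'
#' Signal intervals not absorbed by [extend_genes()] (i.e. not overlapping
#' any gene on the same strand, once genes have been extended) and strictly
#' longer than `min_len` bp are kept; same-scaffold, same-strand survivors
#' within `fuse_gap` bp of each other are merged transitively
#' (single-linkage over the gap graph) into one novel gene model each.
#'
#' @param peaks signal-interval tibble.
#' @param genes gene-model tibble, typically the [extend_genes()] output
#'   (extension absorbs the used peaks into their genes).
#' @param min_len minimum peak length in bp, strict `>` (default 100).
#' @param fuse_gap fuse peaks with gap at most this many bp (default 4500,
#'   a typical median gene size).
#' @return Gene-model tibble of novel models with deterministic ids
#'   `novel_<seqid><strand>_<ordinal>` and `source = "novel"`.
#' @export
orphan_intervals <- function(peaks, genes, min_len = 100, fuse_gap = 4500) {
  peaks <- validate_intervals(peaks, "peak")
  genes <- validate_intervals(genes, "gene")
  len <- peaks$end - peaks$start + 1
  keep <- len > min_len
  for (j in seq_len(nrow(peaks))) {
    if (!keep[j]) next
    same <- genes$seqid == peaks$seqid[j] & genes$strand == peaks$strand[j]
    if (any(same & genes$start <= peaks$end[j] & genes$end >= peaks$start[j])) {
      keep[j] <- FALSE
    }
  }
  surv <- peaks[keep, , drop = FALSE]
  if (!nrow(surv)) {
    return(tibble::tibble(seqid = character(), start = numeric(),
                          end = numeric(), strand = character(),
                          gene = character(), source = character()))
  }
  surv |>
    dplyr::group_by(.data$seqid, .data$strand) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(
      prev_end = dplyr::lag(cummax(.data$end)),
      new_block = is.na(.data$prev_end) |
        interval_gap(.data$prev_end, .data$start) > fuse_gap,
      block = cumsum(.data$new_block)
    ) |>
    dplyr::group_by(.data$seqid, .data$strand, .data$block) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop_last") |>
    dplyr::mutate(gene = paste0("novel_", .data$seqid, .data$strand, "_",
                                dplyr::row_number()),
                  source = "novel") |>
    dplyr::ungroup() |>
    dplyr::select("seqid", "start", "end", "strand", "gene", "source") |>
    dplyr::arrange(.data$seqid, .data$start)
}
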