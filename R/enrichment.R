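#' Read a GMT annotation file
#'
#' One term per line: term id, description, then member ids, tab-separated.
#'
#' @param path GMT file path.
#' @return named list of member-id character vectors; descriptions kept as
#'   attribute `"description"`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  attr(sets, "description") <- vapply(parts, `[`, character(1), 2)
  sets
}

#' Write a GMT annotation file
#'
#' @param sets named list of member-id vectors.
#' @param path output path.
#' @param description per-term descriptions (recycled).
#' @export
write_gmt <- function(sets, path, description = "") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each annotation term, tests whether the gene list overlaps the term
#' more than expected under sampling without replacement from the universe:
#' p = P\[X >= k\] with X ~ Hypergeometric(N, K, n), followed by
#' Benjamini-Hochberg adjustment across terms. Genes outside the universe
#' are excluded with a warning naming them.
#'
#' @param gene_list character vector of ids to test.
#' @param annotation named list of term member vectors (e.g. [read_gmt()]).
#' @param universe background id set; defaults to the union of all
#'   annotation members.
#' @return data.frame of class `enrichment_result`, sorted by p: term, k
#'   (overlap), n (list size), K (term size), N (universe size), p, padj,
#'   overlap_ids.
#' @export
enrich <- function(gene_list, annotation, universe = NULL) {
  if (is.null(universe)) universe <- unique(unlist(annotation))
  universe <- unique(universe)
  gene_list <- unique(gene_list)
  outside <- setdiff(gene_list, universe)
  if (length(outside)) {
    warning("excluded ", length(outside), " id(s) outside the universe: ",
            paste(utils::head(outside, 5), collapse = ", "),
            if (length(outside) > 5) ", ...")
    gene_list <- intersect(gene_list, universe)
  }
  N <- length(universe)
  n <- length(gene_list)
  rows <- lapply(names(annotation), function(tm) {
    members <- intersect(annotation[[tm]], universe)
    K <- length(members)
    hit <- intersect(gene_list, members)
    k <- length(hit)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, n = n, K = K, N = N, p = p,
               overlap_ids = paste(sort(hit), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term), c("term", "k", "n", "K", "N", "p",
                                       "padj", "overlap_ids")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment: %d terms, %d at padj < 0.05\n",
              nrow(x), sum(x$padj < 0.05)))
  print(utils::head(as.data.frame(x)[, c("term", "k", "K", "p", "padj")], 10),
        row.names = FALSE)
  invisible(x)
}
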