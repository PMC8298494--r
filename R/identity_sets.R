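#' Derive a cell-type identity gene set from pairwise comparisons
#'
#' A type's identity (ID) genes are the genes upregulated in that type versus
#' each of the other types: the intersection of the upregulated sets from all
#' pairwise comparisons. A gene upregulated against two types but failing the
#' fold-change floor against the third is therefore absent.
#'
#' @param ... Two or more upregulated gene sets (character vectors), one per
#'   pairwise comparison of the focal type against another type. A single
#'   list argument is also accepted.
#' @param type Label of the focal cell type (provenance).
#' @param comparisons Optional character vector naming the comparisons
#'   (provenance; defaults to argument names where present).
#' @return An \code{identity_set}: list with \code{type}, \code{genes}
#'   (unique, in the order of the first set) and \code{provenance}.
#' @export
derive_id_genes <- function(..., type = "unknown", comparisons = NULL) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]])) sets <- sets[[1]]
  if (length(sets) < 2) stop("need at least two upregulated sets")
  sets <- lapply(sets, as.character)
  genes <- Reduce(intersect, sets)
  if (is.null(comparisons)) {
    comparisons <- names(sets)
    if (is.null(comparisons)) comparisons <- paste0("comparison_", seq_along(sets))
  }
  structure(list(type = type, genes = unique(genes),
                 provenance = list(comparisons = comparisons,
                                   set_sizes = lengths(sets))),
            class = "identity_set")
}

#' @exportS3Method base::print
print.identity_set <- function(x, ...) {
  cat(sprintf("identity_set '%s': %d genes from %d comparisons\n",
              x$type, length(x$genes), length(x$provenance$comparisons)))
  if (length(x$genes))
    cat("  ", paste(utils::head(x$genes, 10), collapse = ", "),
        if (length(x$genes) > 10) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Overlap between an upregulated gene list and an identity set
#'
#' Reports how much of a monohormonal type's identity is carried by the genes
#' upregulated in a bihormonal population: the overlap count, the percentage
#' of the ID set covered (\code{pct_of_id}) and the percentage of the
#' upregulated list shared (\code{pct_of_up}). The ID-set size is always
#' taken from the supplied set.
#'
#' @param up Character vector of upregulated genes (e.g. bihormonal vs
#'   monohormonal anchor cells).
#' @param id_set An \code{identity_set} or plain character vector of the
#'   partner type's ID genes.
#' @return An \code{overlap_report}: \code{n_overlap}, \code{n_id},
#'   \code{n_up}, raw \code{pct_of_id}/\code{pct_of_up} and the overlapping
#'   \code{genes}.
#' @export
bihormonal_overlap <- function(up, id_set) {
  id_genes <- if (inherits(id_set, "identity_set")) id_set$genes
              else as.character(id_set)
  up <- unique(as.character(up))
  id_genes <- unique(id_genes)
  if (!length(up) || !length(id_genes)) stop("both gene lists must be non-empty")
  common <- intersect(up, id_genes)
  structure(list(n_overlap = length(common), n_id = length(id_genes),
                 n_up = length(up),
                 pct_of_id = 100 * length(common) / length(id_genes),
                 pct_of_up = 100 * length(common) / length(up),
                 genes = common), class = "overlap_report")
}

#' @exportS3Method base::print
print.overlap_report <- function(x, digits_id = 0, digits_up = 1, ...) {
  cat(sprintf("overlap: %d of %d ID genes (%s%%) | %d of %d upregulated (%s%%)\n",
              x$n_overlap, x$n_id, formatC(round(x$pct_of_id, digits_id),
                                           format = "f", digits = digits_id),
              x$n_overlap, x$n_up, formatC(round(x$pct_of_up, digits_up),
                                           format = "f", digits = digits_up)))
  invisible(x)
}

#' Intersect upregulated gene sets across datasets and species
#'
#' Maps every set into a common gene namespace (uppercase human-style symbols
#' by default, or an explicit ortholog table) and intersects. Genes with no
#' mapping are dropped and counted.
#'
#' @param sets List of two or more character vectors of gene names.
#' @param ortholog_map Optional two-column data.frame (\code{from},
#'   \code{to}) mapping source symbols to the common namespace; symbols not
#'   in the map fall through unchanged when \code{passthrough = TRUE}.
#' @param passthrough Keep unmapped symbols as their uppercase form
#'   (default) instead of dropping them.
#' @param ambiguous Policy for one-to-many mappings: \code{"drop"} the source
#'   gene (default, with a warning) or \code{"expand"} into all targets.
#' @return Character vector: the intersection in the common namespace, with
#'   attribute \code{n_unmapped} counting dropped symbols per set.
#' @export
cross_dataset_intersection <- function(sets, ortholog_map = NULL,
                                       passthrough = TRUE,
                                       ambiguous = c("drop", "expand")) {
  ambiguous <- match.arg(ambiguous)
  if (length(sets) < 2) stop("need at least two sets")
  map_one <- function(genes) {
    genes <- as.character(genes)
    if (is.null(ortholog_map)) return(list(mapped = toupper(genes), dropped = 0L))
    stopifnot(all(c("from", "to") %in% names(ortholog_map)))
    tab <- split(ortholog_map$to, ortholog_map$from)
    amb <- names(tab)[lengths(tab) > 1]
    mapped <- character(0); dropped <- 0L
    for (g in genes) {
      if (g %in% amb) {
        if (ambiguous == "expand") mapped <- c(mapped, toupper(tab[[g]]))
        else dropped <- dropped + 1L
      } else if (!is.null(tab[[g]])) {
        mapped <- c(mapped, toupper(tab[[g]]))
      } else if (passthrough) {
        mapped <- c(mapped, toupper(g))
      } else dropped <- dropped + 1L
    }
    list(mapped = unique(mapped), dropped = dropped)
  }
  mapped <- lapply(sets, map_one)
  dropped <- vapply(mapped, `[[`, 0L, "dropped")
  if (any(dropped) && ambiguous == "drop")
    warning(sum(dropped), " gene(s) dropped (ambiguous or unmapped)")
  out <- Reduce(intersect, lapply(mapped, `[[`, "mapped"))
  attr(out, "n_unmapped") <- dropped
  out
}

#' Direction-concordant pathways between two datasets
#'
#' Keeps only the pathways present in both tables with the very same
#' direction of modulation (activated in both, or inhibited in both);
#' discordant and one-sided pathways are reported separately. Pathway names
#' are compared case- and whitespace-insensitively.
#'
#' @param table_a,table_b data.frames with columns \code{pathway},
#'   \code{direction} (\code{"activated"}/\code{"inhibited"}) and optional
#'   \code{score}.
#' @return List with data.frames \code{concordant}, \code{discordant} and
#'   \code{one_sided}.
#' @export
pathway_concordance <- function(table_a, table_b) {
  norm <- function(tb, tag) {
    stopifnot(all(c("pathway", "direction") %in% names(tb)))
    tb$key <- tolower(gsub("\\s+", " ", trimws(tb$pathway)))
    dir <- tolower(trimws(tb$direction))
    if (!all(dir %in% c("activated", "inhibited")))
      stop("direction must be 'activated' or 'inhibited'")
    tb$direction <- dir
    dup <- tb$key[duplicated(tb$key)]
    for (k in unique(dup)) {
      if (length(unique(tb$direction[tb$key == k])) > 1)
        stop("conflicting directions for pathway '", k, "' in table ", tag)
    }
    tb[!duplicated(tb$key), , drop = FALSE]
  }
  a <- norm(table_a, "A"); b <- norm(table_b, "B")
  common <- intersect(a$key, b$key)
  ia <- match(common, a$key); ib <- match(common, b$key)
  same <- a$direction[ia] == b$direction[ib]
  concordant <- data.frame(pathway = a$pathway[ia][same],
                           direction = a$direction[ia][same],
                           stringsAsFactors = FALSE)
  discordant <- data.frame(pathway = a$pathway[ia][!same],
                           direction_a = a$direction[ia][!same],
                           direction_b = b$direction[ib][!same],
                           stringsAsFactors = FALSE)
  one_sided <- data.frame(
    pathway = c(a$pathway[!a$key %in% common], b$pathway[!b$key %in% common]),
    source = c(rep("A", sum(!a$key %in% common)),
               rep("B", sum(!b$key %in% common))),
    stringsAsFactors = FALSE)
  list(concordant = concordant, discordant = discordant, one_sided = one_sided)
}

#' Read a one-gene-per-line list file
#'
#' @param path File with an optional \code{#}-prefixed header line naming the
#'   set; blank lines ignored.
#' @return Character vector of genes; the header (if any) is attached as
#'   attribute \code{"header"}.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path)
  header <- NULL
  if (length(lines) && startsWith(lines[1], "#")) {
    header <- sub("^#\\s*", "", lines[1])
    lines <- lines[-1]
  }
  genes <- trimws(lines[nzchar(trimws(lines))])
  attr(genes, "header") <- header
  genes
}

#' Write a gene list (or identity set) one gene per line
#'
#' @param genes Character vector or \code{identity_set}.
#' @param path Output path.
#' @param header Optional comment header (provenance).
#' @return Invisibly, \code{path}.
#' @export
write_gene_list <- function(genes, path, header = NULL) {
  if (inherits(genes, "identity_set")) {
    if (is.null(header))
      header <- sprintf("%s identity set (%s)", genes$type,
                        paste(genes$provenance$comparisons, collapse = "; "))
    genes <- genes$genes
  }
  lines <- as.character(genes)
  if (!is.null(header)) lines <- c(paste0("# ", header), lines)
  writeLines(lines, path)
  invisible(path)
}
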