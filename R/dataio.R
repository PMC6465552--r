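#' Construct an association dataset
#'
#' Bundles a binary disease-by-microbe adjacency matrix with the ordered
#' disease and microbe name vectors. Rows are diseases, columns are microbes;
#' row `i` is the interaction profile of disease `i`, column `j` the
#' interaction profile of microbe `j`.
#'
#' @param adjacency numeric or logical matrix containing only 0/1, with one
#'   row per disease and one column per microbe.
#' @param disease_names character vector of unique disease names, one per row.
#' @param microbe_names character vector of unique microbe names, one per
#'   column.
#' @return An object of class `association_dataset`: a list with elements
#'   `adjacency` (integer 0/1 matrix with dimnames), `disease_names` and
#'   `microbe_names`.
#' @examples
#' ds <- association_dataset(matrix(c(1, 0, 0, 1), 2),
#'                           c("d1", "d2"), c("m1", "m2"))
#' ds$adjacency
#' @export
association_dataset <- function(adjacency, disease_names, microbe_names) {
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "integer"
  if (!all(adjacency %in% c(0L, 1L))) {
    stop("adjacency must contain only 0/1 values")
  }
  disease_names <- as.character(disease_names)
  microbe_names <- as.character(microbe_names)
  if (nrow(adjacency) != length(disease_names) ||
      ncol(adjacency) != length(microbe_names)) {
    stop("adjacency dimensions do not match name vectors")
  }
  if (anyDuplicated(disease_names)) stop("duplicate disease names")
  if (anyDuplicated(microbe_names)) stop("duplicate microbe names")
  dimnames(adjacency) <- list(disease_names, microbe_names)
  structure(
    list(adjacency = adjacency,
         disease_names = disease_names,
         microbe_names = microbe_names),
    class = "association_dataset"
  )
}

#' @export
print.association_dataset <- function(x, ...) {
  cat(sprintf(
    "association_dataset: %d diseases x %d microbes, %d known associations (density %.3f)\n",
    nrow(x$adjacency), ncol(x$adjacency), sum(x$adjacency),
    mean(x$adjacency)))
  invisible(x)
}

#' Read a disease-microbe association edge list
#'
#' Reads a tab-separated edge list with one known association per line:
#' disease name, microbe name, and optional extra columns (e.g. evidence)
#' which are ignored. Lines starting with `#` and blank lines are skipped.
#' Names are trimmed of surrounding whitespace but are otherwise matched
#' exactly (no case folding, so distinct taxon spellings stay distinct).
#' Duplicate (disease, microbe) pairs collapse to a single association.
#'
#' @param path path to the edge-list file (UTF-8).
#' @return An [association_dataset()] whose disease and microbe orderings
#'   follow first appearance in the file.
#' @seealso [write_associations()], [write_rankings()]
#' @export
read_associations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("no associations in ", path)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield < 2L)) {
    bad <- idx[which(nfield < 2L)[1L]]
    stop(sprintf("malformed line %d in %s: fewer than 2 tab-separated fields",
                 bad, path))
  }
  diseases <- trimws(vapply(fields, `[[`, character(1), 1L))
  microbes <- trimws(vapply(fields, `[[`, character(1), 2L))
  if (any(diseases == "") || any(microbes == "")) {
    bad <- idx[which(diseases == "" | microbes == "")[1L]]
    stop(sprintf("malformed line %d in %s: empty name field", bad, path))
  }
  disease_names <- unique(diseases)
  microbe_names <- unique(microbes)
  A <- matrix(0L, length(disease_names), length(microbe_names))
  A[cbind(match(diseases, disease_names), match(microbes, microbe_names))] <- 1L
  association_dataset(A, disease_names, microbe_names)
}

#' Write an association dataset as an edge list
#'
#' Serializes the known associations back to the tab-separated edge-list
#' format accepted by [read_associations()]. Edges are emitted in an order
#' chosen so that re-reading the file reproduces the dataset's disease and
#' microbe orderings whenever such an order exists (it always does for a
#' dataset that itself came from [read_associations()]): an edge is written
#' only once both its endpoints are either already introduced or next in
#' their respective first-appearance sequences.
#'
#' @param dataset an [association_dataset()].
#' @param path output file path.
#' @param header optional character vector of comment lines (written with a
#'   leading `#`).
#' @return `path`, invisibly.
#' @export
write_associations <- function(dataset, path, header = character()) {
  stopifnot(inherits(dataset, "association_dataset"))
  A <- dataset$adjacency
  edges <- which(A == 1L, arr.ind = TRUE)
  ord <- order_edges_first_appearance(edges, nrow(A), ncol(A))
  edges <- edges[ord, , drop = FALSE]
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(dataset$disease_names[edges[, 1L]],
                   dataset$microbe_names[edges[, 2L]], sep = "\t"), con)
  invisible(path)
}

# Greedy witness ordering: repeatedly emit a "safe" edge, i.e. one whose
# disease is already introduced or is the lowest-index disease not yet
# introduced, and likewise for its microbe. If the first-appearance orders are
# realizable at all, this greedy choice never gets stuck (moving a safe edge
# to the front of any witness sequence preserves realizability).
order_edges_first_appearance <- function(edges, n_d, n_m) {
  n_e <- nrow(edges)
  if (n_e == 0L) return(integer())
  remaining <- rep(TRUE, n_e)
  seen_d <- rep(FALSE, n_d)
  seen_m <- rep(FALSE, n_m)
  next_d <- 1L
  next_m <- 1L
  out <- integer(n_e)
  for (step in seq_len(n_e)) {
    cand <- which(remaining &
                    (seen_d[edges[, 1L]] | edges[, 1L] == next_d) &
                    (seen_m[edges[, 2L]] | edges[, 2L] == next_m))
    if (length(cand) == 0L) {
      # no realizable order: fall back to row-major for the rest
      out[step:n_e] <- which(remaining)[order(edges[remaining, 1L],
                                              edges[remaining, 2L])]
      break
    }
    pick <- cand[order(edges[cand, 1L], edges[cand, 2L])][1L]
    out[step] <- pick
    remaining[pick] <- FALSE
    seen_d[edges[pick, 1L]] <- TRUE
    seen_m[edges[pick, 2L]] <- TRUE
    while (next_d <= n_d && seen_d[next_d]) next_d <- next_d + 1L
    while (next_m <= n_m && seen_m[next_m]) next_m <- next_m + 1L
  }
  out
}

#' Write ranked disease-microbe predictions
#'
#' Writes a tab-separated table with columns `disease`, `microbe`, `score`
#' and `rank`, sorted by descending score with ties broken by (disease index,
#' microbe index) so output is deterministic. Scores are printed with 6
#' significant digits.
#'
#' @param scores an `md_scores` object from [predict_associations()], or a
#'   bare numeric matrix with the dataset's dimensions.
#' @param dataset the [association_dataset()] the scores refer to.
#' @param path output file path.
#' @param only_unknown if `TRUE`, pairs already known (adjacency 1) are
#'   omitted, leaving only novel candidate associations.
#' @param header optional character vector of comment lines.
#' @return The ranking `data.frame`, invisibly.
#' @export
write_rankings <- function(scores, dataset, path, only_unknown = FALSE,
                           header = character()) {
  stopifnot(inherits(dataset, "association_dataset"))
  S <- if (inherits(scores, "md_scores")) scores$scores else as.matrix(scores)
  A <- dataset$adjacency
  if (!identical(dim(S), dim(A))) {
    stop("score matrix dimensions do not match dataset")
  }
  cells <- expand.grid(d = seq_len(nrow(A)), m = seq_len(ncol(A)))
  if (only_unknown) cells <- cells[A[as.matrix(cells)] == 0L, , drop = FALSE]
  sc <- S[as.matrix(cells)]
  ord <- order(-sc, cells$d, cells$m)
  tab <- data.frame(
    disease = dataset$disease_names[cells$d[ord]],
    microbe = dataset$microbe_names[cells$m[ord]],
    score = signif(sc[ord], 6),
    rank = seq_along(ord),
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(format(tab, digits = 6, scientific = FALSE, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
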