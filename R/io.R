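#' Read and write the dense influence-matrix TSV dialect
#'
#' Square matrices are stored as tab-separated values with a header row and a
#' leading column of node names; rows index the target node `i`, columns the
#' source node `j` (`S[i, j]` = influence of `j` on `i`).
#'
#' @param M square matrix.
#' @param path file path.
#' @return `read_influence_tsv()` returns the matrix; the writer returns
#'   `path` invisibly.
#' @export
write_influence_tsv <- function(M, path) {
  check_square(M, "M")
  if (is.null(rownames(M))) {
    nm <- paste0("n", seq_len(nrow(M)))
    dimnames(M) <- list(nm, nm)
  }
  df <- data.frame(node = rownames(M), M, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_influence_tsv
#' @export
read_influence_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df[[1]]
  storage.mode(M) <- "double"
  check_square(M, "matrix in file")
}

#' Read and write trajectory ensembles as long-format TSV
#'
#' Columns: `ensemble_id` (`baseline`, `inert` or `perturbed`),
#' `perturbed_param` (0 when none), `time`, `node`, `value`. Only observed
#' trajectories are serialized; noiseless companions are simulation-internal.
#'
#' @param ens a `trajectory_ensemble`.
#' @param path file path.
#' @return the writer returns `path` invisibly; the reader returns the long
#'   data frame.
#' @export
write_trajectories_tsv <- function(ens, path) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  long_one <- function(X, id, k) {
    data.frame(ensemble_id = id, perturbed_param = k,
               time = rep(ens$times, ncol(X)),
               node = rep(seq_len(ncol(X)), each = nrow(X)),
               value = as.numeric(X))
  }
  parts <- c(list(long_one(ens$baseline, "baseline", 0L),
                  long_one(ens$inert, "inert", 0L)),
             lapply(seq_along(ens$perturbed), function(k)
               long_one(ens$perturbed[[k]], "perturbed", k)))
  write.table(do.call(rbind, parts), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories_tsv
#' @export
read_trajectories_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE)
}

#' Read and write gold-standard edge lists
#'
#' Three-column edge lists in the DREAM-challenge style: source node, target
#' node, indicator 1. [edge_list_to_adjacency()] converts to the package's
#' matrix convention (`A[target, source] = 1`).
#'
#' @param adjacency binary matrix (`A[i, j] = 1` for an arc `j -> i`).
#' @param path file path.
#' @param nodes optional node-name vector for the conversion.
#' @param edges data frame with columns source, target.
#' @return the writer returns `path` invisibly; [read_edge_list()] a data
#'   frame; [edge_list_to_adjacency()] the adjacency matrix.
#' @export
write_edge_list <- function(adjacency, path) {
  check_square(adjacency, "adjacency")
  nm <- rownames(adjacency)
  if (is.null(nm)) nm <- paste0("n", seq_len(nrow(adjacency)))
  idx <- which(adjacency != 0, arr.ind = TRUE)
  df <- data.frame(source = nm[idx[, 2]], target = nm[idx[, 1]], present = 1L)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("source", "target", "present"))
  df
}

#' @rdname write_edge_list
#' @export
edge_list_to_adjacency <- function(edges, nodes = NULL) {
  if (is.null(nodes))
    nodes <- sort(unique(c(as.character(edges$source),
                           as.character(edges$target))))
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  A[cbind(match(as.character(edges$target), nodes),
          match(as.character(edges$source), nodes))] <- 1
  A
}
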