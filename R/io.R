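#' Read a molecular graph from an edge list or adjacency matrix
#'
#' Two plain-text formats are supported. `edge_list`: one bond per line as
#' two whitespace-separated vertex labels; `#` starts a comment and blank
#' lines are ignored. `adjacency_csv`: a square, binary, symmetric,
#' zero-diagonal 0/1 matrix in CSV; a header row of labels is optional
#' (detected when the first field of the first row is non-numeric), and
#' unlabelled matrices get vertices named `1..p`.
#'
#' @param file path to the input file, or `"-"` for standard input
#' @param format `"edge_list"` or `"adjacency_csv"`
#' @param text optional character vector of lines, used instead of `file`
#' @return a [molecular_graph()]
#' @examples
#' g <- read_graph(text = c("1 2", "2 3", "2 4", "3 4"))
#' graph_size(g)
#' @export
read_graph <- function(file = NULL, format = c("edge_list", "adjacency_csv"),
                       text = NULL) {
  format <- match.arg(format)
  if (is.null(text)) {
    if (is.null(file)) stop("supply `file` or `text`")
    lines <- if (identical(file, "-")) readLines("stdin") else readLines(file)
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  }
  if (format == "edge_list") read_edge_list(lines) else read_adjacency_csv(lines)
}

read_edge_list <- function(lines) {
  stripped <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(stripped)))
  pairs <- matrix(character(0), ncol = 2L)
  for (ln in keep) {
    toks <- strsplit(trimws(stripped[ln]), "[[:space:]]+")[[1]]
    if (length(toks) != 2L) {
      stop(sprintf("edge list parse error at line %d: expected two labels, got %d",
                   ln, length(toks)))
    }
    pairs <- rbind(pairs, toks)
  }
  if (nrow(pairs) == 0L) stop("edge list contains no edges")
  molecular_graph(pairs)
}

read_adjacency_csv <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("adjacency CSV is empty")
  first <- strsplit(lines[[1]], ",", fixed = TRUE)[[1]]
  # header of labels: non-numeric first row, or one more line than columns
  has_header <- suppressWarnings(anyNA(as.numeric(trimws(first)))) ||
    length(lines) == length(first) + 1L
  if (has_header) {
    labels <- trimws(first)
    body <- lines[-1L]
  } else {
    labels <- NULL
    body <- lines
  }
  rows <- lapply(seq_along(body), function(r) {
    vals <- suppressWarnings(as.numeric(trimws(strsplit(body[[r]], ",", fixed = TRUE)[[1]])))
    if (anyNA(vals)) {
      stop(sprintf("adjacency CSV format error at data row %d: non-numeric entry", r))
    }
    vals
  })
  n <- length(rows)
  if (any(lengths(rows) != n)) stop("adjacency CSV is not square")
  A <- do.call(rbind, rows)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (length(labels) != n) stop("adjacency CSV header length does not match matrix size")
  if (!all(A %in% c(0, 1))) stop("adjacency matrix must be binary (0/1)")
  if (!isTRUE(all.equal(A, t(A)))) stop("adjacency matrix must be symmetric")
  if (any(diag(A) != 0)) stop("adjacency matrix must have a zero diagonal (no self-loops)")
  idx <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  edges <- cbind(labels[idx[, 1L]], labels[idx[, 2L]])
  molecular_graph(edges, vertices = labels)
}

#' Write a molecular graph as text
#'
#' The `edge_list` output is canonical (lexicographic by sorted endpoint
#' pair) and round-trips bit-identically through [read_graph()]. The
#' `adjacency_csv` output carries a header row of vertex labels.
#'
#' @param g a `molecular_graph`
#' @param format `"edge_list"` or `"adjacency_csv"`
#' @param file optional path; when `NULL` the text is returned only
#' @return character vector of output lines, invisibly when written to file
#' @export
write_graph <- function(g, format = c("edge_list", "adjacency_csv"), file = NULL) {
  stopifnot(inherits(g, "molecular_graph"))
  format <- match.arg(format)
  lines <- if (format == "edge_list") {
    paste(g$edges[, 1L], g$edges[, 2L])
  } else {
    A <- graph_matrices(g)$adjacency
    c(paste(g$vertices, collapse = ","),
      apply(A, 1L, function(r) paste(r, collapse = ",")))
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
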