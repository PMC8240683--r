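#' Assemble a community set tibble
#'
#' The package represents a set of communities as a tibble with one row per
#' community: `id`, a `nodes` list-column of character vectors, `size`, an
#' optional `score`, and a `label` (`"positive"`, `"negative"`, or
#' `"learned"`). All community-level verbs take and return this shape so
#' they chain with the pipe.
#'
#' @param node_sets list of character vectors (one per community).
#' @param label provenance label, recycled over rows.
#' @param score optional numeric score vector.
#' @param id optional character ids; generated when missing.
#' @return a community tibble.
#' @export
community_set <- function(node_sets, label = "positive", score = NA_real_,
                          id = NULL) {
  node_sets <- lapply(node_sets, function(x) sort(unique(as.character(x))))
  n <- length(node_sets)
  tibble(
    id = id %||% sprintf("%s_%04d", substr(label, 1, 3), seq_len(n)),
    nodes = node_sets,
    size = lengths(node_sets),
    score = rep_len(score, n),
    label = rep_len(label, n)
  )
}

#' Read communities from a text file
#'
#' One community per line, whitespace-separated node identifiers. A trailing
#' TAB-separated numeric field written by [write_communities()] for scored
#' sets is recognised and read back into `score`.
#'
#' @param path file path.
#' @param label provenance label for all rows.
#' @return a community tibble.
#' @export
read_communities <- function(path, label = "positive") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(paste0("no communities in ", path))
  score <- rep(NA_real_, length(lines))
  tab_split <- strsplit(lines, "\t", fixed = TRUE)
  has_score <- lengths(tab_split) >= 2 &
    !is.na(suppressWarnings(as.numeric(vapply(tab_split, function(p) p[length(p)], ""))))
  score[has_score] <- as.numeric(
    vapply(tab_split[has_score], function(p) p[length(p)], ""))
  node_part <- ifelse(has_score,
                      vapply(tab_split, `[`, "", 1L),
                      lines)
  community_set(strsplit(trimws(node_part), "[ \t]+"),
                label = label, score = score)
}

#' Write communities to a text file
#'
#' @param comms a community tibble.
#' @param path output file path.
#' @param with_score append a TAB-separated score column when scores exist.
#' @return `path`, invisibly.
#' @export
write_communities <- function(comms, path, with_score = !all(is.na(comms$score))) {
  body <- vapply(comms$nodes, paste, "", collapse = " ")
  if (with_score) {
    body <- paste(body, format(comms$score, digits = 8, trim = TRUE), sep = "\t")
  }
  writeLines(body, path)
  invisible(path)
}

#' Jaccard coefficient of two node sets
#'
#' @param a,b character vectors (node sets); must be nonempty.
#' @return `|a ∩ b| / |a ∪ b|`.
#' @export
jaccard <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) abort("jaccard: empty node set")
  a <- unique(a); b <- unique(b)
  i <- length(intersect(a, b))
  i / (length(a) + length(b) - i)
}

#' Neighbourhood-affinity overlap of two node sets
#'
#' The asymmetry-penalising overlap `|a ∩ b|^2 / (|a| * |b|)`, used as the
#' default measure when merging learned communities.
#'
#' @inheritParams jaccard
#' @return a value in \[0, 1\].
#' @export
qi_overlap <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) abort("qi_overlap: empty node set")
  i <- length(intersect(a, b))
  i^2 / (length(unique(a)) * length(unique(b)))
}

# internal: extract list of node sets from a community tibble or plain list
as_node_sets <- function(x) {
  if (is.data.frame(x)) {
    stopifnot("nodes" %in% names(x))
    x$nodes
  } else if (is.list(x)) {
    lapply(x, as.character)
  } else {
    abort("expected a community tibble or a list of node vectors")
  }
}

overlap_fun <- function(measure = c("jaccard", "qi_overlap")) {
  measure <- match.arg(measure)
  if (measure == "jaccard") jaccard else qi_overlap
}
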