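#' Construct a prior knowledge network from a signed edge table
#'
#' A prior knowledge network (PKN) is a signed directed graph of known
#' regulatory interactions among proteins. Node roles are derived from the
#' topology: *stimuli* have no predecessors (the entry layer), *readouts*
#' have no successors (the measured output layer), and *inhibitors* are all
#' remaining intermediate nodes connecting stimuli to readouts.
#'
#' @param edges a data frame with columns `source`, `sign` (+1 or -1) and
#'   `target`, one row per interaction.
#' @return an object of class `pkn`: a list with `nodes` (character),
#'   `edges` (tibble with columns source, sign, target) and `roles`
#'   (named character vector, one of `"stimulus"`, `"inhibitor"`,
#'   `"readout"` per node).
#' @details Duplicate rows are collapsed with a warning. Self-loops are
#'   permitted but flagged with a warning; they are excluded later from
#'   hypergraph expansion, since a node cannot appear as its own regulator
#'   in an AND clause.
#' @examples
#' pkn(tibble::tibble(source = c("A", "C"), sign = c(1, -1),
#'                    target = c("B", "B")))
#' @export
pkn <- function(edges) {
  stopifnot(is.data.frame(edges))
  if (!all(c("source", "sign", "target") %in% names(edges))) {
    stop("`edges` must have columns source, sign, target", call. = FALSE)
  }
  if (nrow(edges) == 0L) stop("no edges", call. = FALSE)
  edges <- tibble::tibble(
    source = as.character(edges$source),
    sign = as.integer(edges$sign),
    target = as.character(edges$target)
  )
  if (!all(edges$sign %in% c(1L, -1L))) {
    bad <- unique(edges$sign[!edges$sign %in% c(1L, -1L)])
    stop("edge sign must be +1 or -1, found: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(edges$source, edges$sign, edges$target)
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate edge(s) collapsed",
            call. = FALSE)
    edges <- edges[!duplicated(key), ]
  }
  if (any(edges$source == edges$target)) {
    warning("self-loop(s) on: ",
            paste(unique(edges$source[edges$source == edges$target]),
                  collapse = ", "),
            " (kept in the PKN, ignored in hypergraph expansion)",
            call. = FALSE)
  }
  nodes <- sort(unique(c(edges$source, edges$target)))
  net <- structure(list(nodes = nodes, edges = edges, roles = NULL),
                   class = "pkn")
  net$roles <- classify_roles(net)
  net
}

#' Read a signed interaction network from a SIF file
#'
#' Parses the three-column simple interaction format: `source sign target`,
#' whitespace- or tab-separated, one interaction per line.
#'
#' @param path path to the SIF file.
#' @param dialect how the middle field encodes the sign: `"numeric"` expects
#'   `1` / `-1`, `"word"` expects `activates` / `inhibits`.
#' @return a [pkn] object with roles computed from the topology.
#' @export
read_sif <- function(path, dialect = c("numeric", "word")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no edges in ", path, call. = FALSE)
  fields <- strsplit(trimws(lines), "[ \t]+")
  n_fields <- lengths(fields)
  if (any(n_fields != 3L)) {
    stop("malformed SIF line ", which(n_fields != 3L)[1L],
         ": expected 3 fields, got ", n_fields[n_fields != 3L][1L],
         call. = FALSE)
  }
  m <- do.call(rbind, fields)
  sign_tok <- m[, 2L]
  sign <- switch(dialect,
    numeric = ifelse(sign_tok == "1", 1L, ifelse(sign_tok == "-1", -1L, NA)),
    word = ifelse(sign_tok == "activates", 1L,
                  ifelse(sign_tok == "inhibits", -1L, NA))
  )
  if (anyNA(sign)) {
    stop("unknown sign token '", sign_tok[is.na(sign)][1L],
         "' (dialect: ", dialect, ")", call. = FALSE)
  }
  pkn(tibble::tibble(source = m[, 1L], sign = sign, target = m[, 3L]))
}

#' Write a PKN to a SIF file
#'
#' Emits tab-separated `source <TAB> 1|-1 <TAB> target` lines.
#'
#' @param x a [pkn] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(x, path) {
  stopifnot(inherits(x, "pkn"))
  writeLines(paste(x$edges$source, x$edges$sign, x$edges$target, sep = "\t"),
             path)
  invisible(path)
}

#' Assign topological roles to PKN nodes
#'
#' In-degree-0 nodes are stimuli, out-degree-0 nodes are readouts and all
#' remaining nodes are inhibitors. A node with neither predecessors nor
#' successors is isolated and rejected. A network without stimuli (e.g. one
#' whose entry layer sits on a feedback cycle) is allowed with a warning.
#'
#' @param x a [pkn] object (roles may be unset).
#' @return named character vector over all nodes with values `"stimulus"`,
#'   `"inhibitor"` or `"readout"`.
#' @export
classify_roles <- function(x) {
  stopifnot(inherits(x, "pkn"))
  nodes <- x$nodes
  indeg <- as.integer(table(factor(x$edges$target, levels = nodes)))
  outdeg <- as.integer(table(factor(x$edges$source, levels = nodes)))
  isolated <- nodes[indeg == 0L & outdeg == 0L]
  if (length(isolated) > 0L) {
    stop("isolated node(s): ", paste(isolated, collapse = ", "),
         call. = FALSE)
  }
  roles <- ifelse(indeg == 0L, "stimulus",
                  ifelse(outdeg == 0L, "readout", "inhibitor"))
  names(roles) <- nodes
  if (!any(roles == "stimulus")) warning("no stimuli in PKN", call. = FALSE)
  if (!any(roles == "readout")) warning("no readouts in PKN", call. = FALSE)
  roles
}

#' Nodes of a PKN holding a given role
#' @param x a [pkn] object.
#' @param role one of `"stimulus"`, `"inhibitor"`, `"readout"`.
#' @return character vector of node ids.
#' @export
pkn_nodes <- function(x, role = NULL) {
  stopifnot(inherits(x, "pkn"))
  if (is.null(role)) return(x$nodes)
  names(x$roles)[x$roles == role]
}

#' @export
print.pkn <- function(x, ...) {
  tab <- table(x$roles)
  cat("<pkn> ", length(x$nodes), " nodes (",
      sum(x$roles == "stimulus"), " stimuli, ",
      sum(x$roles == "inhibitor"), " inhibitors, ",
      sum(x$roles == "readout"), " readouts), ",
      nrow(x$edges), " signed edges\n", sep = "")
  invisible(x)
}

#' @export
tidy.pkn <- function(x, ...) {
  dplyr::mutate(x$edges,
                source_role = unname(x$roles[.data$source]),
                target_role = unname(x$roles[.data$target]))
}

#' @export
glance.pkn <- function(x, ...) {
  tibble::tibble(
    n_nodes = length(x$nodes),
    n_edges = nrow(x$edges),
    n_stimuli = sum(x$roles == "stimulus"),
    n_inhibitors = sum(x$roles == "inhibitor"),
    n_readouts = sum(x$roles == "readout")
  )
}

#' Expand a PKN into its candidate AND-clause hypergraph
#'
#' Every Boolean network considered by the learner is a subset of the clause
#' catalogue built here. For each non-stimulus node with incoming signed
#' edges, the catalogue holds one single-literal clause per edge and, when
#' `max_inputs = 2`, one two-literal AND conjunction per unordered pair of
#' distinct incoming edges. Several clauses selected on the same target are
#' OR-ed, so a network is an OR-of-ANDs update rule per node. Self-loops are
#' skipped.
#'
#' @param x a [pkn] object.
#' @param max_inputs maximal number of source literals per AND gate (1 or 2).
#' @return an object of class `bn_hypergraph`: list with the `pkn` and a
#'   `clauses` tibble (columns `id`, `target`, `source1`, `sign1`, `source2`,
#'   `sign2`, `label`), in canonical order (target, then sorted literals).
#' @export
expand_hypergraph <- function(x, max_inputs = 2) {
  stopifnot(inherits(x, "pkn"), max_inputs %in% c(1, 2))
  ed <- x$edges[x$edges$source != x$edges$target, ]
  out <- list()
  for (tgt in sort(unique(ed$target))) {
    inc <- ed[ed$target == tgt, ]
    # canonical literal order within the node: by source name, then sign
    inc <- inc[order(inc$source, inc$sign), ]
    d <- nrow(inc)
    singles <- tibble::tibble(target = tgt,
                              source1 = inc$source, sign1 = inc$sign,
                              source2 = NA_character_, sign2 = NA_integer_)
    out[[length(out) + 1L]] <- singles
    if (max_inputs == 2 && d >= 2L) {
      idx <- utils::combn(d, 2L)
      keep <- inc$source[idx[1L, ]] != inc$source[idx[2L, ]]
      if (any(keep)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          target = tgt,
          source1 = inc$source[idx[1L, keep]], sign1 = inc$sign[idx[1L, keep]],
          source2 = inc$source[idx[2L, keep]], sign2 = inc$sign[idx[2L, keep]]
        )
      }
    }
  }
  clauses <- dplyr::bind_rows(out)
  if (nrow(clauses) > 0L) {
    ord <- order(clauses$target, clauses$source1, clauses$sign1,
                 clauses$source2, clauses$sign2, na.last = FALSE,
                 method = "radix")
    clauses <- clauses[ord, ]
    clauses$id <- seq_len(nrow(clauses))
    clauses$label <- clause_label(clauses)
    clauses <- clauses[, c("id", "target", "source1", "sign1",
                           "source2", "sign2", "label")]
  } else {
    clauses <- tibble::tibble(id = integer(), target = character(),
                              source1 = character(), sign1 = integer(),
                              source2 = character(), sign2 = integer(),
                              label = character())
  }
  structure(list(pkn = x, clauses = clauses), class = "bn_hypergraph")
}

clause_label <- function(cl) {
  lit <- function(src, sgn) ifelse(sgn < 0, paste0("!", src), src)
  l1 <- lit(cl$source1, cl$sign1)
  ifelse(is.na(cl$source2), paste0(cl$target, " <- ", l1),
         paste0(cl$target, " <- ", l1, " & ", lit(cl$source2, cl$sign2)))
}

#' @export
print.bn_hypergraph <- function(x, ...) {
  cat("<bn_hypergraph> ", nrow(x$clauses), " candidate clauses over ",
      length(x$pkn$nodes), " nodes; search space ",
      format(search_space_size(x)), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.bn_hypergraph <- function(x, ...) x$clauses

#' Size of the Boolean-network search space
#'
#' The learner explores every subset of the candidate clause catalogue, so
#' the search space holds exactly `2^N` networks for `N` candidate clauses.
#' The count is returned exactly (as an arbitrary-precision decimal string)
#' since `N` routinely exceeds the double-precision range for realistic
#' networks.
#'
#' @param x a `bn_hypergraph`.
#' @return an object of class `bn_search_space` with fields `log2` (N),
#'   `label` (`"2^N"`) and `exact` (exact decimal string).
#' @export
search_space_size <- function(x) {
  stopifnot(inherits(x, "bn_hypergraph"))
  n <- nrow(x$clauses)
  structure(list(log2 = n, label = paste0("2^", n), exact = pow2_decimal(n)),
            class = "bn_search_space")
}

#' @export
format.bn_search_space <- function(x, ...) {
  if (x$log2 <= 64) x$exact else paste0(x$label, " (", x$exact, ")")
}

#' @export
print.bn_search_space <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# exact decimal representation of 2^n via digit-vector doubling
pow2_decimal <- function(n) {
  stopifnot(n >= 0)
  d <- c(1L)  # little-endian decimal digits
  for (k in seq_len(n)) {
    d <- d * 2L
    carry <- 0L
    for (j in seq_along(d)) {
      v <- d[j] + carry
      d[j] <- v %% 10L
      carry <- v %/% 10L
    }
    while (carry > 0L) {
      d <- c(d, carry %% 10L)
      carry <- carry %/% 10L
    }
  }
  paste(rev(d), collapse = "")
}
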