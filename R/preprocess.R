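#' Read a patient measurement table
#'
#' Expects a CSV/TSV with a patient-id first column, a `class` column holding
#' `CR` (complete remission) or `PR` (primary resistant), and one column of
#' continuous measurements per protein.
#'
#' @param path path to the table; the delimiter (comma or tab) is sniffed
#'   from the header line.
#' @return a tibble with columns `patient`, `class`, then proteins.
#' @export
read_patients <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  names(df)[1L] <- "patient"
  validate_patients(tibble::as_tibble(df))
}

validate_patients <- function(data) {
  if (!all(c("patient", "class") %in% names(data))) {
    stop("patient table needs `patient` and `class` columns", call. = FALSE)
  }
  data$patient <- as.character(data$patient)
  if (anyDuplicated(data$patient)) stop("duplicate patient ids", call. = FALSE)
  if (!all(data$class %in% c("CR", "PR"))) {
    stop("class labels must be CR or PR", call. = FALSE)
  }
  meas <- setdiff(names(data), c("patient", "class"))
  vals <- as.matrix(data[meas])
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    stop("measurements must be finite numbers (no missing values)",
         call. = FALSE)
  }
  data
}

#' Binarize input-protein measurements by exact 2-means clustering
#'
#' All continuous values of the stimulus/inhibitor proteins are clustered
#' into two groups by k-means with k = 2 and each measurement inherits its
#' cluster center; centers are rescaled onto \[0,1\] by the min-max range of
#' the clustered values, and a measurement is mapped to 1 when
#' `1 - center <= 0.5` (i.e. its rescaled center is at least 0.5), else 0.
#'
#' One-dimensional 2-means is solved exactly and deterministically: the
#' optimal 2-partition of sorted values is contiguous, so scanning the n - 1
#' split points finds the global within-cluster sum-of-squares minimum
#' without random initialization.
#'
#' @param data patient tibble as returned by [read_patients()].
#' @param input_proteins character vector of protein columns to binarize.
#' @param scope `"global"` pools every measurement of every input protein
#'   into one clustering (the default); `"per-protein"` clusters each protein
#'   column separately (useful when protein scales differ).
#' @param seed unused by the exact solver; accepted so call sites can carry
#'   one seed through the whole pipeline.
#' @return an integer 0/1 matrix, patients x input proteins, with dimnames.
#' @export
binarize_inputs <- function(data, input_proteins,
                            scope = c("global", "per-protein"), seed = NULL) {
  scope <- match.arg(scope)
  data <- validate_patients(data)
  if (length(input_proteins) == 0L) stop("empty input protein list",
                                         call. = FALSE)
  missing <- setdiff(input_proteins, names(data))
  if (length(missing) > 0L) {
    stop("input proteins absent from data: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  vals <- as.matrix(data[input_proteins])
  rownames(vals) <- data$patient
  if (scope == "global") {
    bits <- matrix(binarize_vector(as.vector(vals)), nrow = nrow(vals))
    dimnames(bits) <- dimnames(vals)
  } else {
    bits <- apply(vals, 2L, binarize_vector)
    if (nrow(vals) == 1L) bits <- matrix(bits, nrow = 1L)
    dimnames(bits) <- dimnames(vals)
  }
  storage.mode(bits) <- "integer"
  bits
}

# exact 1-D 2-means on a numeric vector -> 0/1 bits per element
binarize_vector <- function(v) {
  if (length(unique(v)) < 2L) {
    warning("constant value set: binarized to all zeros", call. = FALSE)
    return(rep(0L, length(v)))
  }
  split <- exact_two_means(v)
  centers01 <- (split$centers - min(v)) / (max(v) - min(v))
  bit_of_cluster <- as.integer(1 - centers01 <= 0.5)
  bit_of_cluster[split$assignment]
}

# exact 2-means in one dimension: scan contiguous split points of the sorted
# values, minimizing total within-cluster sum of squares.
# returns cluster centers (low, high) and per-element assignment (1 = low).
exact_two_means <- function(v) {
  ord <- order(v)
  s <- v[ord]
  n <- length(s)
  cs <- cumsum(s)
  cs2 <- cumsum(s^2)
  m <- seq_len(n - 1L)
  sse_left <- cs2[m] - cs[m]^2 / m
  sse_right <- (cs2[n] - cs2[m]) - (cs[n] - cs[m])^2 / (n - m)
  best <- which.min(sse_left + sse_right)
  assignment <- integer(n)
  assignment[ord] <- ifelse(seq_len(n) <= best, 1L, 2L)
  centers <- c(cs[best] / best, (cs[n] - cs[best]) / (n - best))
  list(centers = centers, assignment = assignment)
}

#' Normalize readout measurements onto \[0,1\]
#'
#' Each readout value `r'` is mapped to `(r' - min) / (max - min)`. By
#' default `min` and `max` are taken over all readout values of all patients;
#' `scope = "per-protein"` normalizes each readout column by its own range.
#'
#' @param data patient tibble as returned by [read_patients()].
#' @param readout_proteins character vector of readout columns.
#' @param scope `"global"` (default) or `"per-protein"`.
#' @return a numeric matrix in \[0,1\], patients x readouts, with dimnames.
#' @export
normalize_readouts <- function(data, readout_proteins,
                               scope = c("global", "per-protein")) {
  scope <- match.arg(scope)
  data <- validate_patients(data)
  missing <- setdiff(readout_proteins, names(data))
  if (length(missing) > 0L) {
    stop("readout proteins absent from data: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(data[readout_proteins])
  rownames(vals) <- data$patient
  norm1 <- function(x) {
    rng <- range(x)
    if (rng[1] == rng[2]) stop("degenerate readout range (max = min)",
                               call. = FALSE)
    (x - rng[1]) / (rng[2] - rng[1])
  }
  if (scope == "global") {
    out <- matrix(norm1(as.vector(vals)), nrow = nrow(vals))
    dimnames(out) <- dimnames(vals)
    out
  } else {
    out <- apply(vals, 2L, norm1)
    if (nrow(vals) == 1L) out <- matrix(out, nrow = 1L)
    dimnames(out) <- dimnames(vals)
    out
  }
}

#' Preprocess a patient table against a PKN
#'
#' Binarizes the stimulus/inhibitor measurements ([binarize_inputs()]) and
#' normalizes the readout measurements ([normalize_readouts()]) for the
#' proteins shared between the table and the network. Proteins measured but
#' absent from the PKN are dropped with a warning; PKN nodes without
#' measurements are retained downstream as latent intermediates.
#'
#' @param data patient tibble ([read_patients()]).
#' @param network a [pkn] object.
#' @param input_scope,readout_scope clustering/normalization scope, see
#'   [binarize_inputs()] and [normalize_readouts()].
#' @param seed carried through to [binarize_inputs()].
#' @return an object of class `processed_patients`: list with `inputs`
#'   (binary matrix), `readouts` (matrix in \[0,1\]), `labels` (named
#'   character), `patients` (character).
#' @export
process_patients <- function(data, network,
                             input_scope = c("global", "per-protein"),
                             readout_scope = c("global", "per-protein"),
                             seed = NULL) {
  stopifnot(inherits(network, "pkn"))
  data <- validate_patients(data)
  meas <- setdiff(names(data), c("patient", "class"))
  unknown <- setdiff(meas, network$nodes)
  if (length(unknown) > 0L) {
    warning("measured proteins absent from the PKN ignored: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  inputs <- intersect(meas, c(pkn_nodes(network, "stimulus"),
                              pkn_nodes(network, "inhibitor")))
  readouts <- intersect(meas, pkn_nodes(network, "readout"))
  if (length(inputs) == 0L) stop("no measured stimulus/inhibitor proteins",
                                 call. = FALSE)
  if (length(readouts) == 0L) stop("no measured readout proteins",
                                   call. = FALSE)
  new_processed_patients(
    inputs = binarize_inputs(data, inputs, scope = match.arg(input_scope),
                             seed = seed),
    readouts = normalize_readouts(data, readouts,
                                  scope = match.arg(readout_scope)),
    labels = stats::setNames(data$class, data$patient)
  )
}

new_processed_patients <- function(inputs, readouts, labels) {
  stopifnot(nrow(inputs) == nrow(readouts),
            identical(rownames(inputs), rownames(readouts)),
            all(rownames(inputs) %in% names(labels)))
  structure(list(inputs = inputs, readouts = readouts,
                 labels = labels[rownames(inputs)],
                 patients = rownames(inputs)),
            class = "processed_patients")
}

#' @export
print.processed_patients <- function(x, ...) {
  cat("<processed_patients> ", length(x$patients), " patients (",
      sum(x$labels == "CR"), " CR / ", sum(x$labels == "PR"), " PR), ",
      ncol(x$inputs), " binarized inputs, ", ncol(x$readouts),
      " normalized readouts\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.processed_patients <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(patient = x$patients, class = unname(x$labels)),
    tibble::as_tibble(x$inputs),
    tibble::as_tibble(x$readouts)
  )
}

#' Split a processed dataset by response class
#'
#' @param proc a `processed_patients` object.
#' @return named list with elements `CR` and `PR`, each a
#'   `processed_patients` holding that class's rows (column order preserved).
#' @export
split_by_class <- function(proc) {
  stopifnot(inherits(proc, "processed_patients"))
  out <- lapply(c(CR = "CR", PR = "PR"), function(cl) {
    keep <- proc$labels == cl
    if (!any(keep)) stop("no patients in class ", cl, call. = FALSE)
    new_processed_patients(proc$inputs[keep, , drop = FALSE],
                           proc$readouts[keep, , drop = FALSE],
                           proc$labels[keep])
  })
  out
}

#' Write class experiments as a MIDAS CSV
#'
#' MIDAS is the tabular convention used by logic-model learners for
#' perturbation data: `TR:` columns carry the Boolean treatments (here the
#' shared binarized input profile of each cross-class patient couple), the
#' `DA:ALL` column a single pseudo-time, and `DV:` columns the readout
#' values of the class-appropriate member of the couple.
#'
#' @param proc a `processed_patients` object covering both classes.
#' @param couples tibble with columns `cr_patient`, `pr_patient`.
#' @param class `"CR"` or `"PR"`: whose readouts to emit.
#' @param path output CSV path.
#' @param proteins input proteins to emit as treatments (default: all
#'   binarized columns).
#' @return `path`, invisibly.
#' @export
write_midas <- function(proc, couples, class = c("CR", "PR"), path,
                        proteins = colnames(proc$inputs)) {
  class <- match.arg(class)
  stopifnot(inherits(proc, "processed_patients"))
  pats <- if (class == "CR") couples$cr_patient else couples$pr_patient
  if (nrow(couples) > 0L && !all(pats %in% proc$patients)) {
    stop("couples reference unknown patients", call. = FALSE)
  }
  if (nrow(couples) == 0L) warning("no couples: writing header only",
                                   call. = FALSE)
  tr <- proc$inputs[pats, proteins, drop = FALSE]
  dv <- proc$readouts[pats, , drop = FALSE]
  df <- data.frame(check.names = FALSE,
                   `TR:class:CellLine` = rep(1L, length(pats)))
  names(df) <- paste0("TR:", class, ":CellLine")
  for (p in proteins) df[[paste0("TR:", p)]] <- tr[, p]
  df[["DA:ALL"]] <- rep(1L, length(pats))
  for (r in colnames(dv)) df[[paste0("DV:", r)]] <- dv[, r]
  if (length(pats) == 0L) df <- df[0L, , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a MIDAS CSV written by [write_midas()]
#'
#' @param path MIDAS CSV path.
#' @return list with `inputs` (binary matrix) and `readouts` (matrix),
#'   one row per experiment.
#' @export
read_midas <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  tr <- grep("^TR:", names(df), value = TRUE)
  tr <- tr[!grepl(":CellLine$", tr)]
  dv <- grep("^DV:", names(df), value = TRUE)
  list(inputs = as.matrix(df[tr]) |>
         `colnames<-`(sub("^TR:", "", tr)),
       readouts = as.matrix(df[dv]) |>
         `colnames<-`(sub("^DV:", "", dv)))
}
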