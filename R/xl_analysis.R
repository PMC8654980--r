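#' Read a cross-link table
#'
#' Reads a CSV of residue-pair cross-links with identification scores,
#' filters at a score cutoff (strictly greater, matching the usual
#' XlinkX-style "score > 40" filter) and collapses duplicate pairs -- a
#' cross-link is an unordered residue pair, so (A:10, B:20) and (B:20, A:10)
#' are one record and the best score is kept.
#'
#' @param path CSV file with a header.
#' @param score_cutoff keep records with score strictly greater (default 40).
#' @param columns named character vector mapping the required fields
#'   `chain_a`, `res_a`, `chain_b`, `res_b`, `score` to the file's column
#'   names (for exporter variants).
#' @return data frame of class `xl_table` with columns `chain_a`, `res_a`,
#'   `chain_b`, `res_b`, `score` and `class` (`"inter"` between different
#'   chains, `"intra"` within one).  Pairs are stored in canonical order
#'   (chain, residue ascending).
#' @export
read_crosslinks <- function(path, score_cutoff = 40,
                            columns = c(chain_a = "chain_a", res_a = "res_a",
                                        chain_b = "chain_b", res_b = "res_b",
                                        score = "score")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0)
    return(structure(data.frame(chain_a = character(), res_a = integer(),
                                chain_b = character(), res_b = integer(),
                                score = numeric(), class = character(),
                                stringsAsFactors = FALSE),
                     class = c("xl_table", "data.frame")))
  missing <- setdiff(columns, names(df))
  if (length(missing))
    stop("read_crosslinks: missing column(s): ", paste(missing, collapse = ", "))
  out <- data.frame(chain_a = as.character(df[[columns["chain_a"]]]),
                    res_a = suppressWarnings(as.integer(df[[columns["res_a"]]])),
                    chain_b = as.character(df[[columns["chain_b"]]]),
                    res_b = suppressWarnings(as.integer(df[[columns["res_b"]]])),
                    score = as.numeric(df[[columns["score"]]]),
                    stringsAsFactors = FALSE)
  bad <- which(is.na(out$res_a) | is.na(out$res_b))
  if (length(bad))
    stop("read_crosslinks: non-numeric residue number in row(s) ",
         paste(bad, collapse = ", "))
  if (any(out$res_a <= 0 | out$res_b <= 0))
    stop("read_crosslinks: residue numbers must be positive")
  out <- out[out$score > score_cutoff, , drop = FALSE]
  # canonical unordered-pair order, then best-score collapse
  swap <- out$chain_b < out$chain_a |
    (out$chain_b == out$chain_a & out$res_b < out$res_a)
  tmp <- out[swap, c("chain_b", "res_b", "chain_a", "res_a")]
  out[swap, c("chain_a", "res_a", "chain_b", "res_b")] <- tmp
  out <- out[order(-out$score), , drop = FALSE]
  key <- paste(out$chain_a, out$res_a, out$chain_b, out$res_b)
  out <- out[!duplicated(key), , drop = FALSE]
  out <- out[order(out$chain_a, out$res_a, out$chain_b, out$res_b), , drop = FALSE]
  rownames(out) <- NULL
  out$class <- ifelse(out$chain_a == out$chain_b, "intra", "inter")
  class(out) <- c("xl_table", "data.frame")
  out
}

#' Map cross-links onto a structure
#'
#' Computes the Calpha-Calpha distance of each cross-linked residue pair in
#' the structure.  Records with an unresolved endpoint are unmappable (a
#' state, not an error) and excluded from the summary statistics.  A record
#' is satisfied when its distance is at most `l_0`, the upper distance bound
#' of the cross-linker (~25 A for a lysine-reactive reagent like PhoX).
#'
#' @param records an `xl_table` (or compatible data frame).
#' @param structure a [read_structure()] result.
#' @param l_0 distance limit, A.
#' @return object of class `xl_mapping`: the per-record data frame with
#'   `distance` (NA when unmappable) and `satisfied`, plus summary
#'   attributes `n_mappable`, `mean_distance`, `max_distance`,
#'   `fraction_satisfied`.
#' @export
map_crosslinks <- function(records, structure, l_0 = 25) {
  stopifnot(l_0 > 0)
  n <- nrow(records)
  d <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    d[i] <- tryCatch(
      ca_distance(structure, list(records$chain_a[i], records$res_a[i]),
                  list(records$chain_b[i], records$res_b[i])),
      error = function(e) NA_real_)
  }
  out <- as.data.frame(records)
  out$distance <- d
  out$satisfied <- !is.na(d) & d <= l_0
  mappable <- !is.na(d)
  structure(out, class = c("xl_mapping", "data.frame"),
            l_0 = l_0,
            n_mappable = sum(mappable),
            mean_distance = if (any(mappable)) mean(d[mappable]) else NA_real_,
            max_distance = if (any(mappable)) max(d[mappable]) else NA_real_,
            fraction_satisfied = if (any(mappable))
              mean(d[mappable] <= l_0) else NA_real_)
}

#' @export
print.xl_mapping <- function(x, ...) {
  cat(sprintf("Cross-link mapping: %d records, %d mappable, mean %.2f A, max %.2f A, %.0f%% within %g A\n",
              nrow(x), attr(x, "n_mappable"), attr(x, "mean_distance"),
              attr(x, "max_distance"), 100 * attr(x, "fraction_satisfied"),
              attr(x, "l_0")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Summary statistics of a cross-link mapping
#' @param object an `xl_mapping`.
#' @param ... unused.
#' @return list with `n_mappable`, `mean_distance`, `max_distance`,
#'   `fraction_satisfied`, `l_0`.
#' @export
summary.xl_mapping <- function(object, ...) {
  list(n_mappable = attr(object, "n_mappable"),
       mean_distance = attr(object, "mean_distance"),
       max_distance = attr(object, "max_distance"),
       fraction_satisfied = attr(object, "fraction_satisfied"),
       l_0 = attr(object, "l_0"))
}

#' Weighted contact frequency of bead pairs over an ensemble
#'
#' For each pair, the weighted fraction of frames in which the bead-bead
#' distance is at most `threshold` (uniform weights unless the ensemble
#' carries fitted weights).
#'
#' @param ensemble a `cg_ensemble`.
#' @param pairs data frame with bead-index columns `i`, `j`.
#' @param threshold contact distance, A (default 25, the cross-link limit).
#' @return the `pairs` data frame with a `frequency` column in `[0, 1]`.
#' @export
contact_frequency <- function(ensemble, pairs, threshold = 25) {
  if (n_frames(ensemble) < 1) stop("contact_frequency: empty ensemble")
  w <- .frame_weights(ensemble)
  pairs$frequency <- vapply(seq_len(nrow(pairs)), function(r) {
    d <- bead_distance(ensemble, pairs$i[r], pairs$j[r])
    sum(w[d <= threshold])
  }, numeric(1))
  pairs
}

#' Fraction of frames satisfying all restraints simultaneously
#'
#' @param ensemble a `cg_ensemble`.
#' @param pairs data frame with bead-index columns `i`, `j`.
#' @param threshold distance limit, A.
#' @return weighted fraction of frames with every pair within `threshold`.
#' @export
satisfaction_fraction <- function(ensemble, pairs, threshold = 25) {
  if (n_frames(ensemble) < 1) stop("satisfaction_fraction: empty ensemble")
  w <- .frame_weights(ensemble)
  ok <- rep(TRUE, n_frames(ensemble))
  for (r in seq_len(nrow(pairs)))
    ok <- ok & (bead_distance(ensemble, pairs$i[r], pairs$j[r]) <= threshold)
  sum(w[ok])
}

#' Compare per-pair contact frequencies between two ensembles
#'
#' @param freqA,freqB outputs of [contact_frequency()] (data frames with
#'   `i`, `j`, `frequency`).
#' @return list with `aligned` (shared pairs, columns `freqA`, `freqB`,
#'   `difference`, sorted by `|difference|` descending) and `unshared`
#'   (pairs present in only one input, with a `source` column).
#' @export
compare_ensembles <- function(freqA, freqB) {
  ka <- paste(freqA$i, freqA$j)
  kb <- paste(freqB$i, freqB$j)
  shared <- intersect(ka, kb)
  ia <- match(shared, ka); ib <- match(shared, kb)
  aligned <- data.frame(i = freqA$i[ia], j = freqA$j[ia],
                        freqA = freqA$frequency[ia],
                        freqB = freqB$frequency[ib])
  aligned$difference <- aligned$freqA - aligned$freqB
  aligned <- aligned[order(-abs(aligned$difference)), , drop = FALSE]
  rownames(aligned) <- NULL
  only_a <- freqA[!(ka %in% kb), c("i", "j", "frequency"), drop = FALSE]
  only_b <- freqB[!(kb %in% ka), c("i", "j", "frequency"), drop = FALSE]
  unshared <- rbind(
    if (nrow(only_a)) cbind(only_a, source = "A") else NULL,
    if (nrow(only_b)) cbind(only_b, source = "B") else NULL)
  if (is.null(unshared))
    unshared <- data.frame(i = integer(), j = integer(),
                           frequency = numeric(), source = character())
  rownames(unshared) <- NULL
  list(aligned = aligned, unshared = unshared)
}

#' Write a cross-link mapping as TSV
#'
#' @param mapping an `xl_mapping`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_xl_mapping <- function(mapping, path) {
  utils::write.table(as.data.frame(mapping), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
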