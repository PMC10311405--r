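# tag registry: column name -> c(tag code, PAF type letter)
.paf_tags <- list(score = c("sc", "f"), chunks_used = c("ch", "i"),
                  events_used = c("ev", "i"))
.paf_cols <- c("qname", "qlen", "qstart", "qend", "strand", "tname",
               "tlen", "tstart", "tend", "nmatch", "alen", "mapq")

#' Write mappings as PAF
#'
#' Standard 12-column tab-separated PAF (0-based half-open coordinates);
#' the optional `score`, `chunks_used` and `events_used` columns are
#' appended as `sc:f`, `ch:i` and `ev:i` tags. Unmapped records carry `*`
#' as strand and target name with zero coordinates.
#'
#' @param paf data.frame with the 12 mandatory columns (see
#'   [mappingsToPaf()]).
#' @param path output path.
#' @export
writePaf <- function(paf, path) {
  miss <- setdiff(.paf_cols, names(paf))
  if (length(miss))
    stop("PAF data.frame lacks columns: ", paste(miss, collapse = ", "))
  body <- do.call(paste, c(lapply(.paf_cols, function(cn) {
    v <- paf[[cn]]
    if (is.numeric(v)) formatC(v, format = "d") else as.character(v)
  }), sep = "\t"))
  for (cn in names(.paf_tags)) {
    if (!cn %in% names(paf)) next
    tg <- .paf_tags[[cn]]
    v <- paf[[cn]]
    val <- if (tg[2] == "i") sprintf("%d", as.integer(v))
           else sprintf("%.8g", v)
    body <- paste(body, sprintf("%s:%s:%s", tg[1], tg[2], val), sep = "\t")
  }
  writeLines(body, path)
  invisible(path)
}

#' Read a PAF file
#'
#' Parses the 12 mandatory columns and any typed tags; known tags (`sc:f`,
#' `ch:i`, `ev:i`) come back as the `score`, `chunks_used` and
#' `events_used` columns, other tags as character columns named by their
#' two-letter code.
#'
#' @param path input path.
#' @return data.frame of mapping records.
#' @export
readPaf <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L)
    return(stats::setNames(
      data.frame(matrix(nrow = 0, ncol = length(.paf_cols))), .paf_cols))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 12L))
    stop("malformed PAF line ", which(nf < 12L)[1],
         ": fewer than 12 columns")
  col <- function(i) vapply(parts, `[[`, character(1), i)
  int_col <- function(i) {
    v <- suppressWarnings(as.integer(col(i)))
    if (anyNA(v))
      stop("malformed PAF line ", which(is.na(v))[1],
           ": non-integer in column ", i)
    v
  }
  df <- data.frame(qname = col(1), qlen = int_col(2), qstart = int_col(3),
                   qend = int_col(4), strand = col(5), tname = col(6),
                   tlen = int_col(7), tstart = int_col(8),
                   tend = int_col(9), nmatch = int_col(10),
                   alen = int_col(11), mapq = int_col(12),
                   stringsAsFactors = FALSE)
  tag_cols <- list()
  for (li in seq_along(parts)) {
    fs <- parts[[li]]
    if (length(fs) <= 12L) next
    for (f in fs[13:length(fs)]) {
      m <- regmatches(f, regexec("^([A-Za-z][A-Za-z0-9]):([AifZ]):(.*)$", f))[[1]]
      if (length(m) != 4L)
        stop("malformed PAF tag '", f, "' at line ", li)
      code <- m[2]; type <- m[3]; val <- m[4]
      known <- names(which(vapply(.paf_tags, function(t) t[1] == code,
                                  logical(1))))
      nm <- if (length(known)) known[1] else code
      if (is.null(tag_cols[[nm]]))
        tag_cols[[nm]] <- rep(NA_character_, length(parts))
      tag_cols[[nm]][li] <- val
      attr(tag_cols[[nm]], "type") <- type
    }
  }
  for (nm in names(tag_cols)) {
    v <- tag_cols[[nm]]
    df[[nm]] <- switch(attr(v, "type"),
                       i = as.integer(v), f = as.numeric(v), as.character(v))
  }
  df
}

#' Mapping accuracy summary
#'
#' @param TP,FP,FN non-negative counts.
#' @return list of class `EvalResult` with `TP`, `FP`, `FN`, `precision`
#'   (`TP/(TP+FP)`), `recall` (`TP/(TP+FN)`) and `f1` (`2PR/(P+R)`); a
#'   ratio with a zero denominator is NA.
#' @export
evalResult <- function(TP, FP, FN) {
  P <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  R <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  f1 <- if (!is.na(P) && !is.na(R) && P + R > 0) 2 * P * R / (P + R)
        else NA_real_
  structure(list(TP = TP, FP = FP, FN = FN, precision = P, recall = R,
                 f1 = f1), class = "EvalResult")
}

#' @export
print.EvalResult <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d FN=%d  P=%.4f R=%.4f F1=%.4f\n",
              x$TP, x$FP, x$FN, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Compare mapping calls to ground truth
#'
#' pafstats-style accounting. Reads unmapped in the truth are excluded
#' entirely. For each truth-mapped read, the primary call (highest score,
#' then most matches) is a true positive when it names the same target and
#' strand and its mapping position lies within `tolerance` bases of the
#' truth, a false positive otherwise; truth-mapped reads that are unmapped
#' or absent in the calls are false negatives. The position distance is
#' measured between read origins: a streaming mapper covers only part of
#' the read, so the call is projected back to the read's first base using
#' its query start (`tstart - qstart` vs the truth start on the forward
#' strand, `tend + qstart` vs the truth end on the reverse).
#'
#' @param calls,truth PAF data.frames or file paths.
#' @param tolerance maximum mapping-position distance in bases.
#' @return an [evalResult()].
#' @export
compareToTruth <- function(calls, truth, tolerance = 500) {
  if (is.character(calls)) calls <- readPaf(calls)
  if (is.character(truth)) truth <- readPaf(truth)
  tm <- truth[truth$tname != "*", , drop = FALSE]
  cl <- calls[calls$tname != "*", , drop = FALSE]
  if (nrow(cl) > 1L) {
    key <- if (!is.null(cl$score)) -cl$score else -cl$nmatch
    cl <- cl[order(cl$qname, key, -cl$nmatch), , drop = FALSE]
    cl <- cl[!duplicated(cl$qname), , drop = FALSE]
  }
  m <- match(tm$qname, cl$qname)
  present <- !is.na(m)
  FN <- sum(!present)
  if (!any(present)) return(evalResult(0L, 0L, FN))
  cc <- cl[m[present], , drop = FALSE]
  tt <- tm[present, , drop = FALSE]
  dist <- ifelse(cc$strand == "+",
                 abs((cc$tstart - cc$qstart) - tt$tstart),
                 abs((cc$tend + cc$qstart) - tt$tend))
  tp <- cc$tname == tt$tname & cc$strand == tt$strand & dist <= tolerance
  evalResult(sum(tp), sum(!tp), FN)
}

#' Euclidean distance between two abundance vectors
#'
#' @param estimate,truth abundance vectors; when named, the name sets must
#'   match (order-insensitive), otherwise lengths must match.
#' @return the L2 norm of the difference.
#' @export
abundanceDistance <- function(estimate, truth) {
  if (!is.null(names(estimate)) && !is.null(names(truth))) {
    if (!setequal(names(estimate), names(truth)))
      stop("estimate and truth name different taxa")
    truth <- truth[names(estimate)]
  } else if (length(estimate) != length(truth)) {
    stop("abundance vectors have different dimensions")
  }
  sqrt(sum((estimate - truth)^2))
}
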