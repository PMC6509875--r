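#' Parse position weight matrices from TRANSFAC, JASPAR or MEME text
#'
#' Reads a motif library in one of three matrix dialects, auto-detected
#' from header tokens: MEME minimal format (`MEME version` header,
#' `letter-probability matrix` blocks), TRANSFAC flat files (`P0` column
#' header, numbered position rows, `//` block terminators), or JASPAR
#' (`>id name` headers followed by four `A [ ... ]` rows, or bare
#' four-row `.pfm` blocks in A, C, G, T order).
#'
#' Count matrices are converted to probabilities by adding a pseudocount of
#' 0.5 to every cell and renormalizing each position row; matrices whose
#' rows already sum to 1 pass through untouched with the probability flag
#' set.  The pseudocount prevents zero frequencies from degenerating the
#' information weights of the scanner.
#'
#' @param source path to a motif file, or a character vector of its lines.
#' @param format `"auto"` (default), `"transfac"`, `"jaspar"` or `"meme"`.
#' @return A list of [MotifPWM-class] objects, named by motif id.
#' @export
parsePWMs <- function(source, format = c("auto", "transfac", "jaspar", "meme")) {
  format <- match.arg(format)
  lines <- if (length(source) == 1L && file.exists(source))
    readLines(source, warn = FALSE) else as.character(source)
  lines <- sub("\r$", "", lines)
  if (!any(nzchar(trimws(lines)))) stop("empty motif source")
  if (format == "auto") {
    format <- if (any(grepl("^MEME version", lines))) "meme"
      else if (any(grepl("^P[0O]\\s", lines)) && any(grepl("^//", lines)))
        "transfac"
      else "jaspar"
  }
  pwms <- switch(format,
    transfac = .parseTransfac(lines),
    jaspar = .parseJaspar(lines),
    meme = .parseMeme(lines))
  if (length(pwms) == 0L) stop("no motifs found in ", format, " source")
  stats::setNames(pwms, vapply(pwms, motifId, ""))
}

## Build a MotifPWM from a raw L x 4 matrix; counts get pseudocount 0.5.
.finishPwm <- function(motifId, factorName, mat) {
  if (ncol(mat) != 4L)
    stop("motif '", motifId, "': matrix rows must have 4 values (A, C, G, T)")
  rs <- rowSums(mat)
  if (all(abs(rs - 1) <= 1e-6)) {
    MotifPWM(motifId, mat, factorName, isProbability = TRUE)
  } else {
    mat <- mat + 0.5
    mat <- mat / rowSums(mat)
    MotifPWM(motifId, mat, factorName, isProbability = TRUE)
  }
}

.parseTransfac <- function(lines) {
  blocks <- split(lines, cumsum(c(TRUE, grepl("^//", utils::head(lines, -1L)))))
  out <- list()
  for (blk in blocks) {
    blk <- blk[!grepl("^//", blk)]
    if (!any(grepl("^P[0O]\\s", blk))) next
    getField <- function(tag) {
      hit <- grep(paste0("^", tag, "\\s"), blk, value = TRUE)
      if (length(hit)) trimws(sub(paste0("^", tag, "\\s+"), "", hit[1L]))
      else NA_character_
    }
    id <- getField("ID"); ac <- getField("AC"); na <- getField("NA")
    motifId <- if (!is.na(id)) id else if (!is.na(ac)) ac
      else stop("TRANSFAC block without ID or AC line")
    factorName <- if (!is.na(na)) na else motifId
    p0 <- grep("^P[0O]\\s", blk)[1L]
    rows <- list()
    for (j in seq(p0 + 1L, length(blk))) {
      if (j > length(blk)) break
      tok <- strsplit(trimws(blk[j]), "\\s+")[[1L]]
      if (length(tok) == 0L || !grepl("^\\d+$", tok[1L])) break
      vals <- suppressWarnings(as.numeric(tok[-1L]))
      ## a trailing consensus letter is optional
      if (length(vals) >= 5L && is.na(vals[length(vals)]))
        vals <- vals[-length(vals)]
      if (length(vals) != 4L || any(is.na(vals)))
        stop("motif '", motifId, "', line ", j,
             " of block: expected 4 numeric values, got '", blk[j], "'")
      rows[[length(rows) + 1L]] <- vals
    }
    if (length(rows) == 0L)
      stop("motif '", motifId, "': no position rows after the P0 header")
    out[[length(out) + 1L]] <-
      .finishPwm(motifId, factorName, do.call(rbind, rows))
  }
  out
}

.parseJaspar <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  out <- list()
  parseRows <- function(rows, motifId) {
    labelled <- grepl("^[ACGTacgt]\\s*\\[", rows) | grepl("^[ACGTacgt]\\s", rows)
    vals <- lapply(rows, function(ln) {
      ln2 <- gsub("[][]", " ", ln)
      ln2 <- sub("^\\s*[ACGTacgt]\\s+", " ", paste0(" ", ln2))
      v <- suppressWarnings(as.numeric(strsplit(trimws(ln2), "\\s+")[[1L]]))
      if (any(is.na(v)))
        stop("motif '", motifId, "': unparseable matrix row '", ln, "'")
      v
    })
    lens <- vapply(vals, length, 0L)
    if (length(vals) != 4L || length(unique(lens)) != 1L)
      stop("motif '", motifId,
           "': expected 4 equal-length base rows (A, C, G, T)")
    if (any(labelled)) {
      lab <- toupper(substr(rows, 1L, 1L))
      if (!setequal(lab, c("A", "C", "G", "T")))
        stop("motif '", motifId, "': base labels must be A, C, G, T")
      vals <- vals[match(c("A", "C", "G", "T"), lab)]
    }
    t(do.call(rbind, vals))  # 4 x L input -> L x 4
  }
  if (length(hdr) > 0L) {
    bounds <- c(hdr, length(lines) + 1L)
    for (i in seq_along(hdr)) {
      h <- sub("^>\\s*", "", lines[hdr[i]])
      tok <- strsplit(trimws(h), "\\s+")[[1L]]
      motifId <- tok[1L]
      factorName <- if (length(tok) > 1L) paste(tok[-1L], collapse = " ")
        else motifId
      rows <- lines[seq(bounds[i] + 1L, bounds[i + 1L] - 1L)]
      out[[length(out) + 1L]] <-
        .finishPwm(motifId, factorName, parseRows(rows, motifId))
    }
  } else {
    if (length(lines) %% 4L != 0L)
      stop("headerless .pfm input must contain a multiple of 4 rows")
    for (i in seq_len(length(lines) / 4L)) {
      rows <- lines[(i - 1L) * 4L + 1:4]
      id <- paste0("pfm_", i)
      out[[length(out) + 1L]] <- .finishPwm(id, id, parseRows(rows, id))
    }
  }
  out
}

.parseMeme <- function(lines) {
  motifAt <- grep("^MOTIF\\s", lines)
  out <- list()
  for (i in seq_along(motifAt)) {
    tok <- strsplit(trimws(sub("^MOTIF\\s+", "", lines[motifAt[i]])), "\\s+")[[1L]]
    motifId <- tok[1L]
    factorName <- if (length(tok) > 1L) tok[2L] else motifId
    to <- if (i < length(motifAt)) motifAt[i + 1L] - 1L else length(lines)
    blk <- lines[motifAt[i]:to]
    lpHdr <- grep("letter-probability matrix", blk)
    if (length(lpHdr) == 0L)
      stop("motif '", motifId, "': no letter-probability matrix block")
    w <- suppressWarnings(as.integer(
      sub(".*\\bw=\\s*(\\d+).*", "\\1", blk[lpHdr[1L]])))
    rows <- list()
    for (j in seq(lpHdr[1L] + 1L, length(blk))) {
      if (j > length(blk)) break
      tok <- strsplit(trimws(blk[j]), "\\s+")[[1L]]
      vals <- suppressWarnings(as.numeric(tok))
      if (length(vals) == 0L || any(is.na(vals))) break
      if (length(vals) != 4L)
        stop("motif '", motifId, "', matrix line ", j,
             ": expected 4 probabilities, got ", length(vals))
      rows[[length(rows) + 1L]] <- vals
    }
    if (!is.na(w) && length(rows) != w)
      stop("motif '", motifId, "': header says w=", w, " but ",
           length(rows), " rows found")
    mat <- do.call(rbind, rows)
    ## MEME rows are probabilities; renormalize tiny rounding drift
    mat <- mat / rowSums(mat)
    out[[length(out) + 1L]] <-
      MotifPWM(motifId, mat, factorName, isProbability = TRUE)
  }
  out
}

#' Consensus sequence of a PWM
#'
#' The base with the maximal frequency at each position.
#'
#' @param pwm a [MotifPWM-class].
#' @return A character string of length equal to the motif length.
#' @export
consensusSequence <- function(pwm) {
  stopifnot(is(pwm, "MotifPWM"))
  paste(c("A", "C", "G", "T")[apply(pwm@matrix, 1L, which.max)],
        collapse = "")
}

#' Write a motif library in JASPAR text format
#'
#' @param pwms a list of [MotifPWM-class] objects.
#' @param path output path; when `NULL` the text is returned invisibly
#'   instead of written.
#' @return The text lines, invisibly.
#' @export
writePWMs <- function(pwms, path = NULL) {
  lines <- unlist(lapply(pwms, function(p) {
    m <- t(pwmMatrix(p))  # 4 x L
    c(paste0(">", motifId(p), " ", factorName(p)),
      vapply(1:4, function(b) {
        paste0(c("A", "C", "G", "T")[b], " [ ",
               paste(format(m[b, ], trim = TRUE, digits = 15),
                     collapse = " "), " ]")
      }, ""))
  }), use.names = FALSE)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
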