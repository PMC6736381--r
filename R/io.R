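# File formats: rotasequence FASTA in two dialects (single-character and
# whitespace-separated two-token), a PAML-dat-like model file generalized to
# arbitrary state counts, labeled TSV count matrices, and a TSV alphabet map.

#' Read a rotasequence FASTA alignment
#'
#' Accepts both dialects: single-character lines (one symbol per state) or
#' whitespace-separated two-token codes such as \code{"F1 W3 A-"}. The
#' dialect is auto-detected per file unless forced.
#'
#' @param path file path.
#' @param alphabet a \linkS4class{RotamerAlphabet}.
#' @param dialect \code{"auto"}, \code{"char"} or \code{"token"}.
#' @return a \linkS4class{RotaAlignment}.
#' @export
readRotaFasta <- function(path, alphabet, dialect = c("auto", "char", "token")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records in ", path)
  labels <- sub("^>\\s*", "", lines[hdr])
  labels <- sub("\\s.*$", "", labels)
  if (anyDuplicated(labels)) {
    dup <- labels[duplicated(labels)][1]
    stop("duplicate taxon label '", dup, "' in ", path)
  }
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- vector("list", length(hdr))
  for (i in seq_along(hdr)) {
    body <- lines[seq.int(hdr[i] + 1L, length.out = max(0L, ends[i] - hdr[i]))]
    body <- body[nzchar(trimws(body))]
    txt <- paste(body, collapse = " ")
    d <- dialect
    if (d == "auto")
      d <- if (grepl("[[:space:]]", trimws(paste(body, collapse = "")))
               || any(grepl("[[:space:]]", trimws(body)))) "token" else "char"
    seqs[[i]] <- tryCatch(
      if (d == "token") decodeTokens(alphabet, txt)
      else decodeChars(alphabet, gsub("[[:space:]]", "", txt)),
      error = function(e) stop("record '", labels[i], "' (line ", hdr[i], "): ",
                               conditionMessage(e), call. = FALSE))
  }
  len <- lengths(seqs)
  if (length(unique(len)) != 1L)
    stop("ragged alignment in ", path, ": row lengths ",
         paste(unique(len), collapse = ", "))
  m <- do.call(rbind, seqs)
  rownames(m) <- labels
  rotaAlignment(m, alphabet)
}

#' Write a rotasequence FASTA alignment
#'
#' @param x a \linkS4class{RotaAlignment}.
#' @param path output path.
#' @param dialect \code{"char"} (default) or \code{"token"}.
#' @param width line width for the single-character dialect.
#' @export
writeRotaFasta <- function(x, path, dialect = c("char", "token"), width = 70L) {
  dialect <- match.arg(dialect)
  ab <- x@alphabet
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(x@states))) {
    writeLines(paste0(">", rownames(x@states)[i]), con)
    if (dialect == "char") {
      s <- encodeChars(ab, x@states[i, ])
      starts <- seq(1L, max(1L, nchar(s)), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    } else {
      writeLines(encodeTokens(ab, x@states[i, ]), con)
    }
  }
  invisible(path)
}

# --- model files ----------------------------------------------------------

#' Read a PAML-dat-style model file (generalized to any state count)
#'
#' The body is a lower-triangle exchangeability matrix (row i holding i-1
#' entries, i = 2..n) followed by the n equilibrium frequencies, as in
#' standard empirical amino-acid \code{.dat} files. Optional \code{#}-header
#' lines record the state order (\code{# order:} followed by state tokens)
#' and the time-scaling convention (\code{# scaling:}). Standard 20-state
#' files without headers are read with the amino-acid alphabet; 55-entry
#' files default to the full rotamer alphabet. Frequencies off from 1 by up
#' to 1e-3 are renormalized; larger discrepancies are an error.
#'
#' @param path file path.
#' @param alphabet optional \linkS4class{RotamerAlphabet}; inferred from the
#'   state count or the \code{order} header if omitted.
#' @param rescale override the scaling convention used to rebuild Q from the
#'   exchangeabilities; defaults to the file's \code{scaling} header (or
#'   \code{"superscaled"} when absent).
#' @return a \linkS4class{RateModel}.
#' @export
readModelFile <- function(path, alphabet = NULL, rescale = NULL) {
  lines <- readLines(path)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  scaling <- "superscaled"
  sc <- grep("scaling:", hdr, value = TRUE)
  if (length(sc)) scaling <- trimws(sub(".*scaling:", "", sc[1]))
  orderTokens <- NULL
  or <- grep("order:", hdr, value = TRUE)
  if (length(or))
    orderTokens <- strsplit(trimws(sub(".*order:", "", or[1])), "[[:space:]]+")[[1]]
  body <- lines[!grepl("^\\s*#", lines)]
  nums <- suppressWarnings(as.numeric(unlist(strsplit(trimws(body), "[[:space:]]+"))))
  nums <- nums[!is.na(nums)]
  # total = n(n-1)/2 + n  =>  n = (sqrt(8T+9)-1)/2... solve n^2+n-2T=0
  n <- (-1 + sqrt(1 + 8 * length(nums))) / 2
  if (abs(n - round(n)) > 1e-9)
    stop("model file has ", length(nums),
         " numbers; not a lower triangle plus frequencies for any state count")
  n <- as.integer(round(n))
  if (is.null(alphabet)) {
    if (!is.null(orderTokens)) {
      full <- rotamerAlphabet()
      alphabet <- if (all(orderTokens %in% full@tokens) && n == 55) full
        else if (all(orderTokens %in% maskedAlphabet(full)@tokens) && n == 20)
          maskedAlphabet(full)
        else stop("cannot reconstruct an alphabet from the order header; ",
                  "pass one explicitly")
    } else if (n == 55) alphabet <- rotamerAlphabet()
    else if (n == 20) alphabet <- maskedAlphabet(rotamerAlphabet())
    else stop("state count ", n, " needs an explicit alphabet")
  }
  if (length(alphabet@labels) != n)
    stop("alphabet has ", length(alphabet@labels), " states but file has ", n)
  nTri <- n * (n - 1L) / 2L
  tri <- nums[seq_len(nTri)]
  freqs <- nums[nTri + seq_len(n)]
  if (any(tri < 0)) stop("negative exchangeabilities in ", path)
  if (any(freqs < 0)) stop("negative frequencies in ", path)
  if (abs(sum(freqs) - 1) > 1e-3 + 1e-12)
    stop("frequencies sum to ", format(sum(freqs)), "; beyond tolerance 1e-3")
  freqs <- freqs / sum(freqs)
  # reconstruct the symmetric S in file row order
  Sf <- matrix(0, n, n)
  k <- 0L
  for (i in 2:n) {
    Sf[i, seq_len(i - 1L)] <- tri[k + seq_len(i - 1L)]
    k <- k + i - 1L
  }
  Sf <- Sf + t(Sf)
  if (!is.null(orderTokens)) {
    if (length(orderTokens) != n) stop("order header length mismatch")
    idx <- match(orderTokens, alphabet@tokens)
    if (anyNA(idx)) stop("order header does not match the alphabet")
    S <- matrix(0, n, n); S[idx, idx] <- Sf
    f <- numeric(n); f[idx] <- freqs
    freqs <- f
  } else S <- Sf
  dimnames(S) <- list(alphabet@labels, alphabet@labels)
  if (is.null(rescale)) rescale <- scaling
  exchToRateModel(S, freqs, alphabet, rescale = rescale)
}

#' Write a model file (lower-triangle exchangeabilities plus frequencies)
#'
#' @param model a \linkS4class{RateModel}.
#' @param path output path.
#' @param digits significant digits to print.
#' @export
writeModelFile <- function(model, path, digits = 12L) {
  ab <- model@alphabet
  n <- length(ab@labels)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    paste("# rotasub model file; states:", n),
    paste("# scaling:", model@scaling),
    paste("# order:", paste(ab@tokens, collapse = " "))), con)
  S <- model@S
  for (i in 2:n)
    writeLines(paste(format(S[i, seq_len(i - 1L)], digits = digits,
                            trim = TRUE, scientific = TRUE), collapse = " "), con)
  writeLines("", con)
  writeLines(paste(format(model@pi, digits = digits, trim = TRUE,
                          scientific = TRUE), collapse = " "), con)
  invisible(path)
}

# --- count matrices and alphabet map --------------------------------------

#' Write a labeled count matrix as TSV
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @export
writeCountsTSV <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read a labeled count matrix from TSV
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
readCountsTSV <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                              check.names = FALSE))
}

#' Write the alphabet mapping table (label, single char, two-token code)
#' @param alphabet a \linkS4class{RotamerAlphabet}.
#' @param path output path.
#' @export
writeAlphabetMap <- function(alphabet, path) {
  df <- data.frame(label = alphabet@labels, char = alphabet@chars,
                   token = alphabet@tokens, aa = alphabet@aa,
                   rotamer = alphabet@rot)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
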