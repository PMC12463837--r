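#' Construct a gloss-aligned wordlist
#'
#' A wordlist is a varieties-by-glosses table of orthographic word forms: one
#' row per language variety, one column per gloss (a standardized meaning
#' such as "water" or "two"), with `NA` marking a missing form.  It is the
#' raw input of the lexical-distance pipeline.
#'
#' Forms are normalized before storage (see [normalize_form()]): Unicode NFC,
#' case-folded to lower case, outer whitespace stripped and inner whitespace
#' runs collapsed to a single space.  A form that is empty after
#' normalization becomes missing.  Multi-word forms are kept verbatim; when a
#' cell lists several synonyms separated by `/`, only the first is kept.
#'
#' @param forms character matrix with row names = variety identifiers and
#'   column names = gloss identifiers; `NA` = missing form.
#' @param family optional character vector of language-family labels, either
#'   named by variety or in row order.
#' @param normalize normalize the forms (default `TRUE`); set `FALSE` only
#'   for forms already normalized.
#' @return An object of class `"wordlist"`: a list with elements `varieties`,
#'   `glosses`, `forms` (the normalized character matrix) and `family`
#'   (named character vector or `NULL`).
#' @examples
#' f <- rbind(Kikuyu = c(water = "mai", two = "igiri"),
#'            Luhya  = c(water = "amatsi", two = "tsibili"))
#' wordlist(f)
#' @export
wordlist <- function(forms, family = NULL, normalize = TRUE) {
  if (!is.matrix(forms) || !is.character(forms))
    stop("`forms` must be a character matrix")
  varieties <- rownames(forms)
  glosses <- colnames(forms)
  if (is.null(varieties) || is.null(glosses))
    stop("`forms` must have variety row names and gloss column names")
  check_ids(varieties, "variety")
  check_ids(glosses, "gloss")
  if (anyDuplicated(tolower(varieties)))
    stop("variety identifiers are not unique after case-folding: ",
         paste(unique(varieties[duplicated(tolower(varieties))]), collapse = ", "))
  if (normalize) {
    forms[] <- normalize_form(forms)
  }
  forms[!is.na(forms) & forms == ""] <- NA_character_
  if (!is.null(family)) {
    if (is.null(names(family))) {
      if (length(family) != length(varieties))
        stop("`family` must be named by variety or have one entry per variety")
      names(family) <- varieties
    }
    missing_fam <- setdiff(varieties, names(family))
    if (length(missing_fam))
      stop("no family label for: ", paste(missing_fam, collapse = ", "))
    family <- as.character(family[varieties])
    names(family) <- varieties
  }
  structure(list(varieties = varieties, glosses = glosses,
                 forms = forms, family = family),
            class = "wordlist")
}

check_ids <- function(x, what) {
  if (length(x) == 0) stop("no ", what, " identifiers (empty table)")
  if (any(is.na(x) | x == "")) stop("empty ", what, " identifier")
  if (anyDuplicated(x))
    stop("duplicate ", what, " identifier: ",
         paste(unique(x[duplicated(x)]), collapse = ", "))
  invisible(x)
}

#' Normalize orthographic word forms
#'
#' Applies the package's orthographic normalization: Unicode NFC composition,
#' lower-case folding, trimming of leading/trailing whitespace and collapsing
#' of internal whitespace runs to one space.  When a cell holds several
#' variants separated by `/`, the first variant is kept.  Edit distances are
#' computed on these normalized strings so that encoding artifacts (combining
#' characters, stray spaces, case) do not inflate distances.
#'
#' @param x character vector (`NA` passed through).
#' @return character vector of the same length.
#' @export
normalize_form <- function(x) {
  out <- x
  ok <- !is.na(out)
  v <- out[ok]
  v <- sub("/.*$", "", v)                  # first synonym variant only
  v <- stringi::stri_trans_nfc(v)
  v <- stringi::stri_trans_tolower(v)
  v <- gsub("[[:space:]]+", " ", v)
  v <- trimws(v)
  out[ok] <- v
  out
}

#' Read a wordlist from a delimited table
#'
#' Expects a header row of gloss identifiers, variety identifiers in the
#' first column, and optionally a `family` column as the second column.
#' Cells matching one of `missing_tokens` (after trimming) are treated as
#' missing.  The delimiter is auto-detected between comma and tab unless
#' given.
#'
#' @param path path to a CSV/TSV file.
#' @param missing_tokens character vector of cell values meaning "missing";
#'   default `c("", "NA", "?")`.
#' @param delim field delimiter, `","` or `"\t"`; `NULL` (default) to
#'   auto-detect from the header line.
#' @return A [wordlist()] object.
#' @export
read_wordlist <- function(path, missing_tokens = c("", "NA", "?"),
                          delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty file: ", path)
  if (is.null(delim)) {
    delim <- if (lengths(regmatches(lines[1], gregexpr("\t", lines[1]))) > 0)
      "\t" else ","
  }
  rows <- lapply(lines, function(l)
    scan(text = l, what = character(), sep = delim, quote = "\"",
         quiet = TRUE, blank.lines.skip = FALSE,
         na.strings = character(0)))
  header <- rows[[1]]
  if (length(rows) < 2) stop("no varieties: file has a header row only")
  nfield <- length(header)
  ragged <- which(lengths(rows[-1]) != nfield)
  if (length(ragged))
    stop("ragged row ", ragged[1] + 1L, ": expected ", nfield,
         " fields, found ", length(rows[[ragged[1] + 1L]]))
  body <- do.call(rbind, rows[-1])
  has_family <- nfield >= 2 && tolower(trimws(header[2])) == "family"
  first_gloss <- if (has_family) 3L else 2L
  if (first_gloss > nfield) stop("no gloss columns found")
  varieties <- trimws(body[, 1])
  glosses <- trimws(header[first_gloss:nfield])
  forms <- body[, first_gloss:nfield, drop = FALSE]
  forms[trimws(forms) %in% missing_tokens] <- NA_character_
  dimnames(forms) <- list(varieties, glosses)
  family <- if (has_family) {
    fam <- trimws(body[, 2])
    names(fam) <- varieties
    fam
  }
  wordlist(forms, family = family)
}

#' Write a wordlist to a delimited table
#'
#' Inverse of [read_wordlist()]: header of glosses, variety in column 1,
#' family (if present) in column 2, missing forms written as empty cells.
#'
#' @param w a [wordlist()].
#' @param path output path.
#' @param delim field delimiter (default comma).
#' @export
write_wordlist <- function(w, path, delim = ",") {
  stopifnot(inherits(w, "wordlist"))
  forms <- w$forms
  forms[is.na(forms)] <- ""
  df <- data.frame(variety = w$varieties, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(w$family)) df$family <- unname(w$family[w$varieties])
  df <- cbind(df, as.data.frame(forms, stringsAsFactors = FALSE,
                                check.names = FALSE))
  utils::write.table(df, path, sep = delim, row.names = FALSE,
                     qmethod = "double", fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.wordlist <- function(x, ...) {
  n_missing <- sum(is.na(x$forms))
  cat("Wordlist: ", length(x$varieties), " varieties x ",
      length(x$glosses), " glosses (", n_missing, " missing forms)\n",
      sep = "")
  if (!is.null(x$family))
    cat("Families: ", paste(names(table(x$family)), table(x$family),
                            sep = "=", collapse = ", "), "\n", sep = "")
  cat("Varieties: ", paste(utils::head(x$varieties, 8), collapse = ", "),
      if (length(x$varieties) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}
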