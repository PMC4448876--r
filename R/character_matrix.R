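# Discrete character matrices --------------------------------------------
#
# Cell encoding (a plain character matrix underneath):
#   "2"    single state (integer symbol 0-9)
#   "02"   polymorphic cell, the set {0, 2} (digits sorted, unique)
#   NA     missing ("?")
#   "-"    inapplicable (gap); treated as missing in all computation but
#          preserved distinctly for storage and round-trips

MD_INAPP <- "-"

#' Construct a discrete character matrix
#'
#' @param data character matrix, rows = taxa, columns = characters, cells
#'   encoded as digit strings (`"1"`), digit-set strings for polymorphisms
#'   (`"01"`), `NA` for missing and `"-"` for inapplicable. Row names are
#'   taxon labels; column names are character ids (defaulted to
#'   `c1, c2, ...`).
#' @param ordered logical vector, one flag per character; ordered characters
#'   are treated as linear transition series (cost `|a - b|`).
#' @param partition optional character vector of per-character partition
#'   labels (e.g. `"morphology"`, `"gap"`).
#' @param nstates optional integer vector of declared state counts per
#'   character; defaults to the largest observed state + 1 (minimum 2).
#'
#' @return An object of class `char_matrix` with components `taxa`, `data`,
#'   `ordered`, `partition` and `nstates`.
#' @export
character_matrix <- function(data, ordered = NULL, partition = NULL,
                             nstates = NULL) {
  if (!is.matrix(data) || !is.character(data))
    stop("`data` must be a character matrix")
  if (is.null(rownames(data)))
    stop("`data` must have row names (taxon labels)")
  if (anyDuplicated(rownames(data)))
    stop("duplicate taxon label: ",
         paste(unique(rownames(data)[duplicated(rownames(data))]),
               collapse = ", "))
  if (is.null(colnames(data)))
    colnames(data) <- paste0("c", seq_len(ncol(data)))
  nc <- ncol(data)
  if (is.null(ordered)) ordered <- rep(FALSE, nc)
  if (length(ordered) == 1L) ordered <- rep(ordered, nc)
  stopifnot(length(ordered) == nc)
  if (!is.null(partition)) stopifnot(length(partition) == nc)

  # normalise cells: sort/unique polymorphism digits, validate symbols
  for (j in seq_len(nc)) {
    col <- data[, j]
    bad <- !is.na(col) & col != MD_INAPP & !grepl("^[0-9]+$", col)
    if (any(bad))
      stop("undeclared state symbol '", col[bad][1L], "' (taxon ",
           rownames(data)[bad][1L], ", character ", colnames(data)[j], ")")
    poly <- !is.na(col) & col != MD_INAPP & nchar(col) > 1L
    if (any(poly))
      col[poly] <- vapply(strsplit(col[poly], ""), function(s)
        paste(sort(unique(s)), collapse = ""), character(1))
    data[, j] <- col
  }

  observed_max <- apply(data, 2, function(col) {
    st <- unlist(strsplit(col[!is.na(col) & col != MD_INAPP], ""))
    if (!length(st)) -1L else max(as.integer(st))
  })
  if (is.null(nstates)) nstates <- pmax(observed_max + 1L, 2L)
  if (any(observed_max + 1L > nstates))
    stop("observed state exceeds declared state count for character ",
         colnames(data)[which(observed_max + 1L > nstates)[1L]])

  structure(list(taxa = rownames(data), data = data,
                 ordered = as.logical(ordered), partition = partition,
                 nstates = as.integer(nstates)),
            class = "char_matrix")
}

#' @export
print.char_matrix <- function(x, ...) {
  cat("Discrete character matrix:", length(x$taxa), "taxa x",
      ncol(x$data), "characters\n")
  cat("  ordered characters:", sum(x$ordered), "\n")
  aud <- audit_matrix(x)
  cat(sprintf("  missing+inapplicable: %.1f%%\n", 100 * aud$missing_fraction))
  invisible(x)
}

# integer state set of one cell; missing/inapplicable -> full state range
cell_states <- function(cell, k) {
  if (is.na(cell) || cell == MD_INAPP) return(0:(k - 1L))
  as.integer(strsplit(cell, "")[[1L]])
}

is_missing_cell <- function(cells) is.na(cells) | cells == MD_INAPP

#' Read a discrete character matrix
#'
#' Reads NEXUS (DATA or CHARACTERS block, interleaved or not, with
#' polymorphisms as `{..}` or `(..)`, `?` missing and `-` inapplicable;
#' ordered-character flags from an ASSUMPTIONS `TYPESET`/`ctype` statement)
#' or a simple TSV fallback (first column `taxon`, one column per
#' character, cells encoded as in [character_matrix()] with `?` for
#' missing).
#'
#' @param path file to read.
#' @param format `"nexus"`, `"tsv"`, or `"auto"` (by extension).
#' @return a [character_matrix()].
#' @export
read_character_matrix <- function(path, format = c("auto", "nexus", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE))
      "tsv" else "nexus"
  if (format == "tsv") read_matrix_tsv(path) else read_matrix_nexus(path)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          na.strings = "?")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  character_matrix(m)
}

# -- NEXUS ----------------------------------------------------------------

nexus_strip_comments <- function(txt) gsub("\\[[^]]*\\]", "", txt)

read_matrix_nexus <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!grepl("#NEXUS", txt, ignore.case = TRUE))
    stop("not a NEXUS file: ", path)
  txt <- nexus_strip_comments(txt)

  block <- function(name) {
    m <- regmatches(txt, regexpr(
      paste0("(?is)begin\\s+", name, "\\s*;.*?end\\s*;"), txt, perl = TRUE))
    if (length(m)) m[[1L]] else NULL
  }
  blk <- block("data")
  if (is.null(blk)) blk <- block("characters")
  if (is.null(blk)) stop("no DATA or CHARACTERS block in ", path)

  grab <- function(pat, text = blk) {
    m <- regmatches(text, regexpr(pat, text, perl = TRUE, ignore.case = TRUE))
    if (length(m)) m[[1L]] else NULL
  }
  dim_line <- grab("dimensions[^;]*;")
  if (is.null(dim_line)) stop("NEXUS block has no DIMENSIONS statement")
  num_after <- function(key, line) {
    m <- regmatches(line, regexpr(paste0("(?i)", key, "\\s*=\\s*[0-9]+"),
                                  line, perl = TRUE))
    if (!length(m)) return(NA_integer_)
    as.integer(sub(".*=\\s*", "", m))
  }
  ntax <- num_after("ntax", dim_line)
  nchar_decl <- num_after("nchar", dim_line)

  fmt_line <- grab("format[^;]*;")
  missing_sym <- "?"; gap_sym <- "-"; symbols <- NULL
  if (!is.null(fmt_line)) {
    ms <- grab("missing\\s*=\\s*\\S", fmt_line)
    if (!is.null(ms)) missing_sym <- substr(ms, nchar(ms), nchar(ms))
    gs <- grab("gap\\s*=\\s*\\S", fmt_line)
    if (!is.null(gs)) gap_sym <- substr(gs, nchar(gs), nchar(gs))
    sy <- grab('symbols\\s*=\\s*"[^"]*"', fmt_line)
    if (!is.null(sy))
      symbols <- strsplit(gsub('[^0-9A-Za-z]', "", sub("(?i)symbols\\s*=", "",
                          sy, perl = TRUE)), "")[[1L]]
  }

  mat_m <- regmatches(blk, regexpr("(?is)matrix\\s.*?;", blk, perl = TRUE))
  if (!length(mat_m)) stop("NEXUS block has no MATRIX statement")
  body <- sub("(?is)^matrix\\s", "", mat_m[[1L]], perl = TRUE)
  body <- sub(";\\s*$", "", body)
  lines <- strsplit(body, "\n")[[1L]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  taxa <- character(0)
  rows <- list()
  for (ln in lines) {
    if (grepl("^'", ln)) {
      lab <- sub("^'([^']*)'.*$", "\\1", ln)
      seqpart <- sub("^'[^']*'", "", ln)
    } else {
      lab <- sub("\\s.*$", "", ln)
      seqpart <- sub("^\\S+", "", ln)
    }
    seqpart <- gsub("\\s", "", seqpart)
    if (!nzchar(lab)) next
    if (!lab %in% taxa) { taxa <- c(taxa, lab); rows[[lab]] <- "" }
    rows[[lab]] <- paste0(rows[[lab]], seqpart)
  }
  if (!is.na(ntax) && length(taxa) != ntax)
    stop("dimension mismatch: NTAX=", ntax, " but ", length(taxa),
         " taxa found in matrix")

  cells <- lapply(taxa, function(tx)
    tokenize_nexus_row(rows[[tx]], tx, missing_sym, gap_sym, symbols))
  ncc <- lengths(cells)
  if (length(unique(ncc)) != 1L)
    stop("unequal row lengths in matrix (taxon ",
         taxa[which(ncc != ncc[1L])[1L]], ")")
  if (!is.na(nchar_decl) && ncc[1L] != nchar_decl)
    stop("dimension mismatch: NCHAR=", nchar_decl, " but ", ncc[1L],
         " characters found")
  m <- do.call(rbind, cells)
  rownames(m) <- taxa
  colnames(m) <- paste0("c", seq_len(ncol(m)))

  ordered <- rep(FALSE, ncol(m))
  ab <- block("assumptions")
  if (is.null(ab)) ab <- block("mrbayes")
  if (!is.null(ab)) {
    stmts <- regmatches(ab, gregexpr(
      "(?i)(typeset[^;]*;|ctype[^;]*;)", ab, perl = TRUE))[[1L]]
    for (st in stmts) {
      segs <- regmatches(st, gregexpr(
        "(?i)(?<![a-z])(ord|ordered)\\s*:\\s*[-0-9 \t]+", st,
        perl = TRUE))[[1L]]
      for (sg in segs) {
        ids <- parse_char_ranges(sub("(?i)^(ord|ordered)\\s*:\\s*", "", sg,
                                     perl = TRUE))
        ordered[ids[ids <= ncol(m)]] <- TRUE
      }
    }
  }
  nst <- if (!is.null(symbols)) rep(length(symbols), ncol(m)) else NULL
  if (!is.null(nst)) {
    obs <- apply(m, 2, function(col) {
      st <- unlist(strsplit(col[!is.na(col) & col != MD_INAPP], ""))
      if (!length(st)) -1L else max(as.integer(st))
    })
    nst <- pmax(obs + 1L, 2L)  # per-character effective range
  }
  character_matrix(m, ordered = ordered, nstates = nst)
}

tokenize_nexus_row <- function(s, taxon, missing_sym, gap_sym, symbols) {
  chars <- strsplit(s, "")[[1L]]
  out <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("{", "(")) {
      close <- if (ch == "{") "}" else ")"
      j <- i + 1L
      set <- character(0)
      while (j <= n && chars[j] != close) {
        if (chars[j] != ",") set <- c(set, chars[j])
        j <- j + 1L
      }
      if (j > n) stop("unterminated polymorphism in row for taxon ", taxon)
      check_symbols(set, taxon, length(out) + 1L, symbols)
      out <- c(out, paste(sort(unique(set)), collapse = ""))
      i <- j + 1L
    } else if (ch == missing_sym) {
      out <- c(out, NA_character_); i <- i + 1L
    } else if (ch == gap_sym) {
      out <- c(out, MD_INAPP); i <- i + 1L
    } else {
      check_symbols(ch, taxon, length(out) + 1L, symbols)
      out <- c(out, ch); i <- i + 1L
    }
  }
  out
}

check_symbols <- function(st, taxon, charnum, symbols) {
  bad <- if (!is.null(symbols)) !st %in% symbols else !grepl("^[0-9]$", st)
  if (any(bad))
    stop("undeclared state symbol '", st[bad][1L], "' (taxon ", taxon,
         ", character ", charnum, ")")
}

parse_char_ranges <- function(s) {
  toks <- strsplit(trimws(s), "[ \t]+")[[1L]]
  out <- integer(0)
  for (tk in toks) {
    if (grepl("-", tk)) {
      ab <- as.integer(strsplit(tk, "-")[[1L]])
      out <- c(out, seq(ab[1L], ab[2L]))
    } else out <- c(out, as.integer(tk))
  }
  out
}

#' Write a character matrix to NEXUS
#'
#' Emits a `#NEXUS` file with a DATA block (polymorphisms in braces, `?`
#' missing, `-` inapplicable) and, when any character is ordered, an
#' ASSUMPTIONS block with a `TYPESET` declaring the ordered characters.
#' `read_character_matrix()` on the result reproduces the matrix
#' cell-for-cell.
#'
#' @param x a [character_matrix()].
#' @param path output file.
#' @export
write_character_matrix <- function(x, path) {
  k <- max(x$nstates)
  syms <- paste(0:(k - 1L), collapse = " ")
  enc_row <- function(cells) paste(vapply(cells, function(cl) {
    if (is.na(cl)) "?"
    else if (cl == MD_INAPP) "-"
    else if (nchar(cl) > 1L) paste0("{", cl, "}")
    else cl
  }, character(1)), collapse = "")
  lab <- sprintf("%-*s", max(nchar(x$taxa)) + 2L,
                 ifelse(grepl("\\s", x$taxa), sQuote(x$taxa, q = FALSE),
                        x$taxa))
  lines <- c("#NEXUS", "", "BEGIN DATA;",
             sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;",
                     length(x$taxa), ncol(x$data)),
             sprintf('  FORMAT DATATYPE=STANDARD SYMBOLS="%s" MISSING=? GAP=-;',
                     syms),
             "  MATRIX",
             paste0("    ", lab,
                    vapply(seq_along(x$taxa), function(i)
                      enc_row(x$data[i, ]), character(1))),
             "  ;", "END;")
  if (any(x$ordered)) {
    ords <- format_char_ranges(which(x$ordered))
    unords <- format_char_ranges(which(!x$ordered))
    ts <- paste0("  TYPESET * default = ord: ", ords,
                 if (nzchar(unords)) paste0(", unord: ", unords), ";")
    lines <- c(lines, "", "BEGIN ASSUMPTIONS;", ts, "END;")
  }
  writeLines(lines, path)
  invisible(path)
}

format_char_ranges <- function(idx) {
  if (!length(idx)) return("")
  idx <- sort(idx)
  runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
  paste(vapply(runs, function(r)
    if (length(r) == 1L) as.character(r)
    else paste0(r[1L], "-", r[length(r)]), character(1)), collapse = " ")
}

#' Write a character matrix as TSV
#' @param x a [character_matrix()].
#' @param path output file.
#' @export
write_character_matrix_tsv <- function(x, path) {
  m <- x$data
  m[is.na(m)] <- "?"
  df <- data.frame(taxon = x$taxa, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# -- audit ----------------------------------------------------------------

#' Audit a character matrix
#'
#' Counts taxa and characters (per partition when partition labels are
#' present), the missing-data fraction, and the invariant characters among
#' a taxon subset. Missing and inapplicable cells both count as missing in
#' `missing_fraction`; `missing_fraction_qmark` counts only true `?` cells
#' (the two conventions bracket what a published "percent missing" may
#' mean). A character is invariant iff the union of its observed state
#' sets (polymorphic cells contributing all their states) has at most one
#' element.
#'
#' @param x a [character_matrix()].
#' @param taxa optional subset of taxon labels (default: all).
#' @return a `matrix_audit` list: `n_taxa`, `n_characters`,
#'   `n_characters_by_partition`, `missing_fraction`,
#'   `missing_fraction_qmark`, `invariant_characters` (character ids).
#' @export
audit_matrix <- function(x, taxa = NULL) {
  stopifnot(inherits(x, "char_matrix"))
  if (is.null(taxa)) taxa <- x$taxa
  if (!length(taxa)) stop("empty taxon subset")
  miss <- setdiff(taxa, x$taxa)
  if (length(miss)) stop("unknown taxa: ", paste(miss, collapse = ", "))
  m <- x$data[taxa, , drop = FALSE]

  n_cells <- length(m)
  n_missing <- sum(is.na(m) | m == MD_INAPP)
  n_qmark <- sum(is.na(m))

  inv <- vapply(seq_len(ncol(m)), function(j) {
    st <- unique(unlist(strsplit(m[, j][!is_missing_cell(m[, j])], "")))
    length(st) <= 1L
  }, logical(1))

  by_part <- if (!is.null(x$partition)) table(x$partition) else NULL
  structure(list(
    n_taxa = length(taxa),
    n_characters = ncol(m),
    n_characters_by_partition = by_part,
    missing_fraction = n_missing / n_cells,
    missing_fraction_qmark = n_qmark / n_cells,
    invariant_characters = colnames(m)[inv]
  ), class = "matrix_audit")
}

#' @export
print.matrix_audit <- function(x, ...) {
  cat("Matrix audit:", x$n_taxa, "taxa x", x$n_characters, "characters\n")
  cat(sprintf("  missing+inapplicable: %.2f%% (missing only: %.2f%%)\n",
              100 * x$missing_fraction, 100 * x$missing_fraction_qmark))
  cat("  invariant characters:", length(x$invariant_characters), "\n")
  invisible(x)
}
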