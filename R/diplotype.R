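#' Parse a star-allele diplotype string
#'
#' Accepts the diplotype grammar used on clinical pharmacogenetic reports:
#' two allele specifications separated by `/`, where each side is a star
#' allele with an optional copy-number suffix `xN` (e.g. `*1x2` for a
#' duplication) or a hybrid tandem joined by `+` (e.g. `*36+*10`). Tandems
#' are kept together as a single allele unit and scored via their dedicated
#' entry in the allele-definition table. The two sides are put in canonical
#' order (lower numeric star value first) so that `*2/*1` and `*1/*2`
#' compare equal.
#'
#' @param text Diplotype string, e.g. `"*1/*4"`, `"*1/*1x2"`, `"*36+*10/*4"`.
#' @param gene `"CYP2C19"` or `"CYP2D6"`.
#' @return An object of class `pgx_diplotype`: a list with `gene`,
#'   `allele1`, `copy1`, `allele2`, `copy2` and the original string in `raw`.
#' @examples
#' parse_diplotype("*1/*2", "CYP2C19")
#' parse_diplotype("*1/*1x2", "CYP2D6")
#' @export
parse_diplotype <- function(text, gene) {
  gene <- match.arg(gene, PGX_GENES)
  if (!is.character(text) || length(text) != 1 || is.na(text) ||
      !nzchar(trimws(text))) {
    stop("diplotype string must be a non-empty character scalar",
         call. = FALSE)
  }
  raw <- text
  text <- gsub("\\s+", "", text)
  sides <- strsplit(text, "/", fixed = TRUE)[[1]]
  if (length(sides) != 2 || any(!nzchar(sides))) {
    stop("malformed diplotype '", raw,
         "': expected two alleles separated by '/'", call. = FALSE)
  }
  parsed <- lapply(sides, parse_allele_side, raw = raw)
  d <- structure(
    list(gene = gene,
         allele1 = parsed[[1]]$allele, copy1 = parsed[[1]]$copy,
         allele2 = parsed[[2]]$allele, copy2 = parsed[[2]]$copy,
         raw = raw),
    class = "pgx_diplotype")
  canonicalize_diplotype(d)
}

# One side of a diplotype: allele[xN] or a '+'-joined hybrid tandem.
parse_allele_side <- function(side, raw) {
  units <- strsplit(side, "+", fixed = TRUE)[[1]]
  if (length(units) == 0 || any(!nzchar(units))) {
    stop("malformed diplotype '", raw, "': empty allele token in '", side,
         "'", call. = FALSE)
  }
  if (length(units) > 1) {
    # hybrid tandem: individual units carry no copy suffix; the tandem is a
    # single allele with copy 1, resolved as a unit against the definitions
    for (u in units) check_allele_token(sub("x[0-9]+$", "", u), raw)
    if (any(grepl("x[0-9]+$", units))) {
      stop("malformed diplotype '", raw,
           "': copy numbers are not supported inside hybrid tandems",
           call. = FALSE)
    }
    return(list(allele = paste(units, collapse = "+"), copy = 1L))
  }
  unit <- units[[1]]
  copy <- 1L
  m <- regmatches(unit, regexec("^(.*?)x([0-9]+)$", unit))[[1]]
  if (length(m) == 3) {
    unit <- m[2]
    copy <- suppressWarnings(as.integer(m[3]))
    if (is.na(copy) || copy < 1) {
      stop("malformed diplotype '", raw, "': copy number must be a positive",
           " integer in '", m[1], "'", call. = FALSE)
    }
  } else if (grepl("x", unit, fixed = TRUE)) {
    stop("malformed diplotype '", raw, "': invalid copy-number suffix in '",
         unit, "'", call. = FALSE)
  }
  check_allele_token(unit, raw)
  list(allele = unit, copy = copy)
}

check_allele_token <- function(token, raw) {
  if (!grepl("^\\*[0-9]+[A-Za-z]*$", token)) {
    stop("malformed diplotype '", raw, "': invalid allele token '", token,
         "'", call. = FALSE)
  }
  invisible(token)
}

# Numeric star value of the leading allele in a (possibly tandem) unit,
# used for the canonical ordering.
allele_sort_key <- function(allele) {
  first <- strsplit(allele, "+", fixed = TRUE)[[1]][1]
  as.numeric(sub("^\\*([0-9]+).*$", "\\1", first))
}

canonicalize_diplotype <- function(d) {
  k1 <- allele_sort_key(d$allele1)
  k2 <- allele_sort_key(d$allele2)
  swap <- (k2 < k1) ||
    (k2 == k1 && d$allele2 < d$allele1) ||
    (k2 == k1 && d$allele2 == d$allele1 && d$copy2 < d$copy1)
  if (swap) {
    d[c("allele1", "copy1", "allele2", "copy2")] <-
      d[c("allele2", "copy2", "allele1", "copy1")]
  }
  d
}

#' Format a diplotype in canonical form
#'
#' @param d A `pgx_diplotype`.
#' @return Canonical string such as `"*1/*1x2"`; parsing it back yields an
#'   identical diplotype (round-trip property).
#' @export
format_diplotype <- function(d) {
  stopifnot(inherits(d, "pgx_diplotype"))
  fmt_side <- function(allele, copy) {
    if (copy > 1) paste0(allele, "x", copy) else allele
  }
  paste0(fmt_side(d$allele1, d$copy1), "/", fmt_side(d$allele2, d$copy2))
}

#' @export
format.pgx_diplotype <- function(x, ...) format_diplotype(x)

#' @export
print.pgx_diplotype <- function(x, ...) {
  cat(x$gene, format_diplotype(x), "\n")
  invisible(x)
}

#' @export
`==.pgx_diplotype` <- function(e1, e2) {
  inherits(e2, "pgx_diplotype") && e1$gene == e2$gene &&
    format_diplotype(e1) == format_diplotype(e2)
}
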