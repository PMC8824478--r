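#' @importFrom rlang .data %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join bind_rows n across all_of distinct rename count pull
#' @importFrom tibble tibble as_tibble
NULL

# Three-letter amino acid codes accepted in HGVS p. notation.
AA3 <- c(
  "Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His", "Ile",
  "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val"
)

# p16^INK4A^ protein length (NP_000068.1).
P16_LENGTH <- 156L

#' Parse HGVS protein-change notation
#'
#' Parses simple HGVS p. strings describing missense changes
#' (e.g. `"p.Gly101Trp"`) or frameshifts (e.g. `"p.Leu78Hisfs*41"`) against
#' the p16^INK4A^ reference NP_000068.1, validating amino acid codes and the
#' codon position (1--156).
#'
#' @param hgvs_p Character vector of HGVS protein-change strings, each
#'   beginning with `"p."`. Stray spaces after `"p."` are tolerated.
#'
#' @return A tibble with one row per input and columns `hgvs_p` (normalized
#'   string), `ref_aa`, `position`, `alt_aa` (three-letter code, or the
#'   frameshift descriptor such as `"Hisfs*41"`), and `variant_class`
#'   (`"missense"` or `"frameshift"`).
#'
#' @examples
#' parse_hgvs_p(c("p.Gly101Trp", "p.Leu78Hisfs*41"))
#' @export
parse_hgvs_p <- function(hgvs_p) {
  stopifnot(is.character(hgvs_p))
  txt <- gsub("^p\\.\\s+", "p.", trimws(hgvs_p))
  bad_prefix <- !startsWith(txt, "p.")
  if (any(bad_prefix)) {
    stop("not HGVS p. notation: ", paste(sQuote(hgvs_p[bad_prefix]), collapse = ", "),
         call. = FALSE)
  }
  body <- substring(txt, 3L)

  re_mis <- "^([A-Z][a-z]{2})(\\d+)([A-Z][a-z]{2})$"
  re_fs  <- "^([A-Z][a-z]{2})(\\d+)([A-Z][a-z]{2}fs\\*\\d+)$"
  is_mis <- grepl(re_mis, body)
  is_fs  <- grepl(re_fs, body)
  if (any(!is_mis & !is_fs)) {
    stop("malformed HGVS p. string: ",
         paste(sQuote(hgvs_p[!is_mis & !is_fs]), collapse = ", "), call. = FALSE)
  }
  re <- ifelse(is_fs, re_fs, re_mis)
  ref_aa <- mapply(function(b, r) sub(r, "\\1", b), body, re, USE.NAMES = FALSE)
  pos    <- as.integer(mapply(function(b, r) sub(r, "\\2", b), body, re, USE.NAMES = FALSE))
  alt_aa <- mapply(function(b, r) sub(r, "\\3", b), body, re, USE.NAMES = FALSE)

  bad_ref <- !(ref_aa %in% AA3)
  fs_new  <- ifelse(is_fs, substr(alt_aa, 1L, 3L), alt_aa)
  bad_alt <- !(fs_new %in% AA3)
  if (any(bad_ref | bad_alt)) {
    off <- unique(c(ref_aa[bad_ref], fs_new[bad_alt]))
    stop("unknown amino acid code: ", paste(sQuote(off), collapse = ", "), call. = FALSE)
  }
  out_of_range <- pos < 1L | pos > P16_LENGTH
  if (any(out_of_range)) {
    stop("codon position outside 1-", P16_LENGTH, " (NP_000068.1): ",
         paste(sQuote(hgvs_p[out_of_range]), collapse = ", "), call. = FALSE)
  }

  tibble(
    hgvs_p = paste0("p.", ref_aa, pos, alt_aa),
    ref_aa = ref_aa,
    position = pos,
    alt_aa = alt_aa,
    variant_class = ifelse(is_fs, "frameshift", "missense")
  )
}

#' Format parsed variant fields back to HGVS p. notation
#'
#' Inverse of [parse_hgvs_p()]: `format_hgvs_p(parse_hgvs_p(x))` reproduces
#' the (normalized) input strings.
#'
#' @param parsed A data frame with columns `ref_aa`, `position`, `alt_aa`
#'   as produced by [parse_hgvs_p()].
#' @return Character vector of HGVS p. strings.
#' @export
format_hgvs_p <- function(parsed) {
  stopifnot(all(c("ref_aa", "position", "alt_aa") %in% names(parsed)))
  paste0("p.", parsed$ref_aa, parsed$position, parsed$alt_aa)
}
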