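#' Structural descriptor of a fatty acid
#'
#' Builds and validates the structural representation used throughout the
#' package: acyl-chain carbon count, number of double bonds, methyl branching
#' (iso = omega-2, anteiso = omega-3), double-bond geometry and position,
#' hydroxyl substituents and ring content.
#'
#' @param carbons integer, number of acyl-chain carbons (>= 2).
#' @param double_bonds integer, number of C=C double bonds (>= 0).
#' @param branch one of `"none"`, `"iso"`, `"anteiso"`, `"other"`.
#' @param geometry one of `"cis"`, `"trans"`, `"unspecified"`. A stated
#'   geometry requires at least one double bond.
#' @param db_position optional position token, e.g. `"n7"` (omega numbering)
#'   or `"7"` (delta numbering, as in `C16:1cis7`). `NA` if unstated.
#' @param hydroxyl_positions integer vector of hydroxylated carbon positions
#'   (may be empty).
#' @param cyclic logical, `TRUE` for cyclopropane/cyclo fatty acids.
#' @param raw_label the label the descriptor was parsed from (kept verbatim).
#'
#' @return An object of class `fa_descriptor`.
#' @seealso [parse_fa_label()], [structural_class()], [chain_length_class()]
#' @export
fa_descriptor <- function(carbons, double_bonds = 0L, branch = "none",
                          geometry = "unspecified", db_position = NA_character_,
                          hydroxyl_positions = integer(), cyclic = FALSE,
                          raw_label = NA_character_) {
  carbons <- as.integer(carbons)
  double_bonds <- as.integer(double_bonds)
  branch <- match.arg(branch, c("none", "iso", "anteiso", "other"))
  geometry <- match.arg(geometry, c("cis", "trans", "unspecified"))
  hydroxyl_positions <- as.integer(hydroxyl_positions)

  if (is.na(carbons) || carbons < 2L)
    stop("fa_descriptor: 'carbons' must be an integer >= 2", call. = FALSE)
  if (is.na(double_bonds) || double_bonds < 0L)
    stop("fa_descriptor: 'double_bonds' must be a non-negative integer", call. = FALSE)
  if (double_bonds >= carbons / 2 + 1)
    stop("fa_descriptor: 'double_bonds' too large for ", carbons, " carbons", call. = FALSE)
  if (branch == "anteiso" && carbons < 5L)
    stop("fa_descriptor: anteiso branching requires >= 5 carbons", call. = FALSE)
  if (geometry != "unspecified" && double_bonds < 1L)
    stop("fa_descriptor: geometry '", geometry,
         "' stated but the acid has no double bond", call. = FALSE)
  if (length(hydroxyl_positions) &&
      (any(is.na(hydroxyl_positions)) ||
       any(hydroxyl_positions < 2L | hydroxyl_positions > carbons)))
    stop("fa_descriptor: hydroxyl positions must lie in 2..carbons", call. = FALSE)

  structure(
    list(raw_label = raw_label, carbons = carbons, double_bonds = double_bonds,
         branch = branch, geometry = geometry, db_position = db_position,
         hydroxyl_positions = sort(hydroxyl_positions), cyclic = isTRUE(cyclic)),
    class = "fa_descriptor")
}

fa_parse_error <- function(label, token, detail) {
  stop(structure(
    class = c("fa_parse_error", "error", "condition"),
    list(message = sprintf("cannot parse fatty-acid label '%s': %s token '%s'",
                           label, detail, token),
         call = NULL)))
}

#' Parse a fatty-acid label into a structural descriptor
#'
#' Understands the common chromatography label dialects: branching prefixes
#' (`"a-"`, `"aC15:0"`, `"anteiso-"`, `"i-"`, `"iso-"`), cyclopropane prefixes
#' (`"cyclo-"`, `"cy-"`), hydroxyl prefixes (`"2OH-"`, `"3OH-"`), the core
#' `C<carbons>:<double bonds>` token, and unsaturation suffixes (`"n7"`,
#' `"n9c"`, `"cis7"`, `"trans9"`, bare `"c"`/`"t"`). Parsing is
#' case-insensitive and tolerant of unicode hyphens.
#'
#' @param label character scalar, e.g. `"a-C15:0"`, `"C18:1n7c"`, `"2OH-C14:0"`.
#' @return An [fa_descriptor()].
#' @section Errors:
#' An unparseable label raises a condition of class `fa_parse_error` naming
#' the offending token; labels are never silently defaulted.
#' @examples
#' parse_fa_label("a-C15:0")
#' parse_fa_label("C18:1n7c")
#' parse_fa_label("2OH-C14:0")
#' @export
parse_fa_label <- function(label) {
  if (!is.character(label) || length(label) != 1L || is.na(label) ||
      !nzchar(trimws(label)))
    stop("parse_fa_label: 'label' must be a non-empty character scalar",
         call. = FALSE)
  raw <- label
  s <- tolower(trimws(label))
  # normalize unicode hyphen variants to ASCII
  s <- gsub("[‐‑‒–—−]", "-", s)
  s <- gsub("\\s+", "", s)

  core <- regmatches(s, gregexpr("c[0-9]+:[0-9]+", s))[[1]]
  if (length(core) != 1L)
    fa_parse_error(raw, s, "missing or ambiguous C<n>:<m> core in")
  pos <- regexpr(core, s, fixed = TRUE)
  pre <- substr(s, 1L, pos - 1L)
  suf <- substr(s, pos + nchar(core), nchar(s))

  nums <- as.integer(strsplit(sub("^c", "", core), ":", fixed = TRUE)[[1]])
  carbons <- nums[1]; dbl <- nums[2]

  branch <- "none"; cyclic <- FALSE; oh <- integer()
  while (nzchar(pre)) {
    m <- regmatches(pre, regexpr("^(anteiso-?|iso-?|cyclo-?|cy-|a-|i-|[0-9]+oh-?|a|i)", pre))
    if (!length(m)) fa_parse_error(raw, pre, "unrecognized prefix")
    tok <- m[1]
    if (grepl("^(a-?|anteiso-?)$", tok)) {
      if (branch != "none") fa_parse_error(raw, tok, "duplicate branch prefix")
      branch <- "anteiso"
    } else if (grepl("^(i-?|iso-?)$", tok)) {
      if (branch != "none") fa_parse_error(raw, tok, "duplicate branch prefix")
      branch <- "iso"
    } else if (grepl("^(cyclo-?|cy-)$", tok)) {
      cyclic <- TRUE
    } else {
      oh <- c(oh, as.integer(sub("oh-?$", "", tok)))
    }
    pre <- substr(pre, nchar(tok) + 1L, nchar(pre))
  }

  geometry <- "unspecified"; db_position <- NA_character_
  if (nzchar(suf)) {
    if (grepl("^n[0-9]+(c|t|cis|trans)?$", suf)) {
      db_position <- regmatches(suf, regexpr("^n[0-9]+", suf))
      g <- sub("^n[0-9]+", "", suf)
      if (nzchar(g)) geometry <- if (g %in% c("c", "cis")) "cis" else "trans"
    } else if (grepl("^(cis|trans)[0-9]+$", suf)) {
      geometry <- if (startsWith(suf, "cis")) "cis" else "trans"
      db_position <- sub("^(cis|trans)", "", suf)
    } else if (suf %in% c("c", "cis")) {
      geometry <- "cis"
    } else if (suf %in% c("t", "trans")) {
      geometry <- "trans"
    } else {
      fa_parse_error(raw, suf, "unrecognized suffix")
    }
  }

  out <- try(fa_descriptor(carbons, dbl, branch, geometry, db_position,
                           oh, cyclic, raw_label = raw), silent = TRUE)
  if (inherits(out, "try-error"))
    fa_parse_error(raw, core, attr(out, "condition")$message)
  out
}

#' @export
format.fa_descriptor <- function(x, ...) {
  pre <- ""
  if (length(x$hydroxyl_positions))
    pre <- paste0(paste0(x$hydroxyl_positions, "OH-", collapse = ""), pre)
  if (x$cyclic) pre <- paste0(pre, "cyclo-")
  if (x$branch == "iso") pre <- paste0(pre, "i-")
  if (x$branch == "anteiso") pre <- paste0(pre, "a-")
  suf <- ""
  if (!is.na(x$db_position)) {
    if (startsWith(x$db_position, "n")) {
      suf <- paste0(x$db_position,
                    switch(x$geometry, cis = "c", trans = "t", ""))
    } else {
      suf <- paste0(if (x$geometry == "trans") "trans" else "cis", x$db_position)
    }
  } else if (x$geometry == "cis") {
    suf <- "c"
  } else if (x$geometry == "trans") {
    suf <- "t"
  }
  paste0(pre, "C", x$carbons, ":", x$double_bonds, suf)
}

#' @export
print.fa_descriptor <- function(x, ...) {
  cat("<fa_descriptor> ", format(x), "\n", sep = "")
  cat("  carbons: ", x$carbons, "  double bonds: ", x$double_bonds,
      "  branch: ", x$branch, "  geometry: ", x$geometry, "\n", sep = "")
  if (!is.na(x$db_position)) cat("  position: ", x$db_position, "\n", sep = "")
  if (length(x$hydroxyl_positions))
    cat("  hydroxyl at: ", paste(x$hydroxyl_positions, collapse = ", "), "\n", sep = "")
  if (x$cyclic) cat("  cyclic\n")
  invisible(x)
}

#' Chain-length class of a fatty acid
#'
#' Classifies by acyl carbon count: short-chain (SCFA, fewer than 6 carbons),
#' medium-chain (MCFA, 7-12), long-chain (LCFA, 13-21) and very-long-chain
#' (VLCFA, 22-24). C6 falls between the stated short- and medium-chain bounds;
#' it is assigned to MCFA by default to keep the classes contiguous.
#'
#' @param d an [fa_descriptor()].
#' @param c6_class class for the 6-carbon boundary case, `"MCFA"` or `"SCFA"`.
#' @return One of `"SCFA"`, `"MCFA"`, `"LCFA"`, `"VLCFA"`, `"out_of_range"`.
#' @export
chain_length_class <- function(d, c6_class = c("MCFA", "SCFA")) {
  stopifnot(inherits(d, "fa_descriptor"))
  c6_class <- match.arg(c6_class)
  n <- d$carbons
  if (n < 6L) "SCFA"
  else if (n == 6L) c6_class
  else if (n <= 12L) "MCFA"
  else if (n <= 21L) "LCFA"
  else if (n <= 24L) "VLCFA"
  else "out_of_range"
}

#' Structural class of a fatty acid
#'
#' Assigns exactly one of the disjoint structural groups used for profile
#' summaries, with fixed precedence: cyclic > hydroxy > polyunsaturated
#' (PUFA) > straight-chain monounsaturated (n-MUFA) > branched saturated
#' (br-SFA) > straight-chain saturated (n-SFA). Branched unsaturated acids do
#' not belong to any of those groups and are returned as `"br_UFA_unknown"`.
#'
#' @param d an [fa_descriptor()].
#' @return One of `"cyclic_FA"`, `"hydroxy_FA"`, `"PUFA"`, `"n_MUFA"`,
#'   `"br_SFA"`, `"n_SFA"`, `"br_UFA_unknown"`.
#' @export
structural_class <- function(d) {
  stopifnot(inherits(d, "fa_descriptor"))
  if (d$cyclic) return("cyclic_FA")
  if (length(d$hydroxyl_positions)) return("hydroxy_FA")
  if (d$double_bonds >= 2L) return("PUFA")
  if (d$double_bonds == 1L && d$branch == "none") return("n_MUFA")
  if (d$double_bonds == 0L && d$branch != "none") return("br_SFA")
  if (d$double_bonds == 0L) return("n_SFA")
  "br_UFA_unknown"
}
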