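#' Acyl chain identity
#'
#' An acyl chain is identified by its carbon count and number of double
#' bonds, written `"C:D"` in the usual lipidomics shorthand (`"18:1"` is
#' oleoyl). Chains are the atoms of the remodeling model: every reaction
#' replaces one chain by another at a fixed sn position.
#'
#' @param carbons Integer carbon count, at least 2.
#' @param double_bonds Integer double-bond count, between 0 and `carbons`.
#' @return An object of class `acyl_chain` with fields `carbons` and
#'   `double_bonds`.
#' @examples
#' acyl_chain(18, 1)
#' parse_chain("22:6")
#' @export
acyl_chain <- function(carbons, double_bonds) {
  if (length(carbons) != 1L || length(double_bonds) != 1L ||
      is.na(carbons) || is.na(double_bonds) ||
      carbons != as.integer(carbons) || double_bonds != as.integer(double_bonds)) {
    stop("carbons and double_bonds must be single integers", call. = FALSE)
  }
  carbons <- as.integer(carbons)
  double_bonds <- as.integer(double_bonds)
  if (carbons < 2L) stop("acyl chain must have at least 2 carbons", call. = FALSE)
  if (double_bonds < 0L || double_bonds > carbons) {
    stop("double_bonds must lie in [0, carbons]", call. = FALSE)
  }
  structure(list(carbons = carbons, double_bonds = double_bonds),
            class = "acyl_chain")
}

#' Parse a "C:D" chain token
#'
#' @param token Character scalar such as `"18:1"`.
#' @return An `acyl_chain`.
#' @export
parse_chain <- function(token) {
  if (length(token) != 1L || is.na(token) ||
      !grepl("^[0-9]+:[0-9]+$", token)) {
    stop(sprintf("malformed acyl chain token '%s': expected 'C:D' with integer C and D",
                 as.character(token)[1]), call. = FALSE)
  }
  parts <- as.integer(strsplit(token, ":", fixed = TRUE)[[1]])
  acyl_chain(parts[1], parts[2])
}

#' @export
format.acyl_chain <- function(x, ...) {
  sprintf("%d:%d", x$carbons, x$double_bonds)
}

#' @export
print.acyl_chain <- function(x, ...) {
  cat("<acyl chain>", format(x), "\n")
  invisible(x)
}

#' @export
`==.acyl_chain` <- function(e1, e2) {
  e1$carbons == e2$carbons && e1$double_bonds == e2$double_bonds
}

#' Diacyl species identity
#'
#' A diacyl species is an ordered pair of acyl chains at the sn1 and sn2
#' positions of the glycerol backbone; `"18:0-22:6"` and `"22:6-18:0"` are
#' distinct positional isomers. Rendered as `"sn1-sn2"`.
#'
#' @param sn1,sn2 `acyl_chain` objects or `"C:D"` tokens.
#' @return An object of class `species_id` with fields `sn1` and `sn2`.
#' @examples
#' species_id("18:0", "22:6")
#' @export
species_id <- function(sn1, sn2) {
  if (is.character(sn1)) sn1 <- parse_chain(sn1)
  if (is.character(sn2)) sn2 <- parse_chain(sn2)
  stopifnot(inherits(sn1, "acyl_chain"), inherits(sn2, "acyl_chain"))
  structure(list(sn1 = sn1, sn2 = sn2), class = "species_id")
}

#' Parse a species label
#'
#' Labels are `"C:D-C:D"` (sn1 chain, separator, sn2 chain). Some MS
#' software writes `"C:D/C:D"`; pass `sep = "/"` for that dialect.
#'
#' @param label Character scalar, e.g. `"18:0-22:6"`.
#' @param sep Single-character chain separator, default `"-"`.
#' @return A `species_id`. `render_species(parse_species(x)) == x`.
#' @examples
#' parse_species("18:3-18:3")
#' parse_species("18:0/22:6", sep = "/")
#' @export
parse_species <- function(label, sep = "-") {
  if (length(label) != 1L || is.na(label)) {
    stop("species label must be a single string", call. = FALSE)
  }
  parts <- strsplit(label, sep, fixed = TRUE)[[1]]
  if (length(parts) != 2L) {
    stop(sprintf("malformed species label '%s': expected two 'C:D' tokens separated by '%s'",
                 label, sep), call. = FALSE)
  }
  sn1 <- tryCatch(parse_chain(parts[1]), error = function(e) {
    stop(sprintf("malformed sn1 chain in '%s': %s", label, conditionMessage(e)),
         call. = FALSE)
  })
  sn2 <- tryCatch(parse_chain(parts[2]), error = function(e) {
    stop(sprintf("malformed sn2 chain in '%s': %s", label, conditionMessage(e)),
         call. = FALSE)
  })
  species_id(sn1, sn2)
}

#' Render a species as its "sn1-sn2" label
#'
#' @param s A `species_id`.
#' @param sep Chain separator, default `"-"`.
#' @return Character scalar.
#' @export
render_species <- function(s, sep = "-") {
  stopifnot(inherits(s, "species_id"))
  paste(format(s$sn1), format(s$sn2), sep = sep)
}

#' @export
format.species_id <- function(x, ...) render_species(x)

#' @export
print.species_id <- function(x, ...) {
  cat("<PE species>", render_species(x), "\n")
  invisible(x)
}

#' @export
`==.species_id` <- function(e1, e2) {
  e1$sn1 == e2$sn1 && e1$sn2 == e2$sn2
}

as_species <- function(x) {
  if (inherits(x, "species_id")) x else parse_species(x)
}

#' Which single sn position distinguishes two species?
#'
#' Remodeling reactions exchange one chain at one position, so two species
#' can be directly connected only if they agree at one sn position and
#' differ at the other.
#'
#' @param a,b `species_id` objects or labels.
#' @return `"sn1"` or `"sn2"` if the species differ at exactly that
#'   position; `NA_character_` if they are identical or differ at both.
#' @examples
#' differs_at_one_position("18:3-18:3", "18:1-18:3")  # "sn1"
#' differs_at_one_position("18:3-18:3", "18:1-18:1")  # NA
#' @export
differs_at_one_position <- function(a, b) {
  a <- as_species(a)
  b <- as_species(b)
  same1 <- a$sn1 == b$sn1
  same2 <- a$sn2 == b$sn2
  if (same1 && !same2) return("sn2")
  if (!same1 && same2) return("sn1")
  NA_character_
}
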