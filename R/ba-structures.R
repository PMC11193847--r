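# Steroid-core encoding of bile acids: hydroxyl/oxo states at C3/C6/C7/C12
# plus the A/B ring-junction configuration at C5. States use short codes:
# "a" = alpha-OH, "b" = beta-OH, "oxo" = ketone, "-" = unsubstituted; c5 is
# "a" (allo, 5alpha) or "b" (normal, 5beta). Side-chain conjugation and
# sulfation are carried as tags and never touched by the ring operators.

.BA_STATES <- c("a", "b", "oxo", "-")

#' Shipped bile-acid structure dictionary
#'
#' Standard steroid nomenclature for the bile acids handled by the
#' biotransformation engine: the 15 mutually increased rumen BAs plus CA,
#' isoUDCA, DCA and the common oxo/epimer relatives. Each row encodes one
#' BA; structures are unique over (c3, c6, c7, c12, c5).
#'
#' @return data.frame with columns name, c3, c6, c7, c12, c5, tags.
#' @export
ba_structures <- function() {
  S <- function(name, c3, c6, c7, c12, c5) {
    data.frame(name = name, c3 = c3, c6 = c6, c7 = c7, c12 = c12, c5 = c5,
               tags = "", stringsAsFactors = FALSE)
  }
  d <- rbind(
    S("CA",                          "a",   "-",   "a",   "a",   "b"),
    S("alloCA",                      "a",   "-",   "a",   "a",   "a"),
    S("UCA",                         "a",   "-",   "b",   "a",   "b"),
    S(paste0("3", .BETA, "-CA"),     "b",   "-",   "a",   "a",   "b"),
    S("3-DHCA",                      "oxo", "-",   "a",   "a",   "b"),
    S("12-DHCA",                     "a",   "-",   "a",   "oxo", "b"),
    S("DHCA",                        "oxo", "-",   "oxo", "oxo", "b"),
    S("CDCA",                        "a",   "-",   "a",   "-",   "b"),
    S("UDCA",                        "a",   "-",   "b",   "-",   "b"),
    S("isoUDCA",                     "b",   "-",   "b",   "-",   "b"),
    S("7-ketoLCA",                   "a",   "-",   "oxo", "-",   "b"),
    S("LCA",                         "a",   "-",   "-",   "-",   "b"),
    S("isoLCA",                      "b",   "-",   "-",   "-",   "b"),
    S("DHLCA",                       "oxo", "-",   "-",   "-",   "b"),
    S("DCA",                         "a",   "-",   "-",   "a",   "b"),
    S("3-epiDCA",                    "b",   "-",   "-",   "a",   "b"),
    S("12-ketoLCA",                  "a",   "-",   "-",   "oxo", "b"),
    S("7-ketoDCA",                   "a",   "-",   "oxo", "a",   "b"),
    S("7,12-diketoLCA",              "a",   "-",   "oxo", "oxo", "b"),
    S("6,7-diketoLCA",               "a",   "oxo", "oxo", "-",   "b"),
    S("HCA",                         "a",   "a",   "a",   "-",   "b"),
    S(paste0(.OMEGA, "-MCA"),        "a",   "a",   "b",   "-",   "b"),
    S(paste0(.ALPHA, "-MCA"),        "a",   "b",   "a",   "-",   "b"),
    S(paste0(.BETA, "-MCA"),         "a",   "b",   "b",   "-",   "b"),
    S("HDCA",                        "a",   "a",   "-",   "-",   "b"),
    S("isoHDCA",                     "b",   "a",   "-",   "-",   "b"),
    S("MDCA",                        "a",   "b",   "-",   "-",   "b"),
    S("6-ketoLCA",                   "a",   "oxo", "-",   "-",   "b")
  )
  rownames(d) <- NULL
  d
}

.validate_structures <- function(dict) {
  stopifnot(is.data.frame(dict),
            all(c("name", "c3", "c6", "c7", "c12", "c5") %in% names(dict)))
  for (col in c("c3", "c6", "c7", "c12")) {
    bad <- !dict[[col]] %in% .BA_STATES
    if (any(bad)) stop("invalid state in column ", col, ": ",
                       paste(unique(dict[[col]][bad]), collapse = ", "))
  }
  if (!all(dict$c5 %in% c("a", "b"))) stop("c5 must be 'a' or 'b'")
  if (anyDuplicated(dict$name)) stop("duplicate structure names")
  key <- .structure_key(dict)
  if (anyDuplicated(key)) {
    stop("duplicate structures: ",
         paste(dict$name[duplicated(key) | duplicated(key, fromLast = TRUE)],
               collapse = ", "))
  }
  invisible(dict)
}

.structure_key <- function(dict) {
  paste(dict$c3, dict$c6, dict$c7, dict$c12, dict$c5, sep = "|")
}

# systematic fallback name for a structure absent from the dictionary
.systematic_name <- function(s) {
  parts <- character(0)
  for (pos in c(3, 6, 7, 12)) {
    st <- s[[paste0("c", pos)]]
    if (st == "a") parts <- c(parts, paste0(pos, .ALPHA, "-OH"))
    if (st == "b") parts <- c(parts, paste0(pos, .BETA, "-OH"))
    if (st == "oxo") parts <- c(parts, paste0(pos, "-oxo"))
  }
  paste0("[", paste(parts, collapse = ","), ",5",
         if (s$c5 == "a") .ALPHA else .BETA, "-BA]")
}

#' Strip conjugation/sulfation tags from a bile-acid species
#'
#' Models bile salt hydrolase (BSH) deconjugation as a tag-stripping
#' utility: glycine/taurine conjugates and 3-sulfates map to their free
#' core BA. The ring operators themselves never act on tagged species.
#'
#' @param names character vector of canonical BA ids.
#' @return character vector of core BA ids.
#' @export
strip_conjugation <- function(names) {
  x <- sub("-3-sulfate$", "", names)
  x <- sub("^(Gly|Glyco|G)(?=[A-Z0-9])", "", x, perl = TRUE)
  x <- sub("^(Tauro|T)(?=[A-Z0-9])", "", x, perl = TRUE)
  normalize_ba_name(x)
}
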