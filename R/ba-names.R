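# Canonical bile-acid nomenclature and the primary/secondary classification
# scheme. Canonical ids keep Greek letters (ω, α, β); an ASCII
# transliteration is available for downstream tools that cannot carry UTF-8.

.OMEGA <- "\u03c9"
.ALPHA <- "\u03b1"
.BETA <- "\u03b2"

# canonical id -> known aliases (all matched case-insensitively after
# whitespace collapse). Long-form names follow standard steroid usage.
.ba_synonyms <- function() {
  syn <- list(
    c("cholic acid"),                                        # CA
    c("allocholic acid"),                                    # alloCA
    c("chenodeoxycholic acid"),                              # CDCA
    c("deoxycholic acid"),                                   # DCA
    c("lithocholic acid"),                                   # LCA
    c("isolithocholic acid"),                                # isoLCA
    c("ursodeoxycholic acid"),                               # UDCA
    c("isoursodeoxycholic acid"),                            # isoUDCA
    c("hyocholic acid"),                                     # HCA
    c("hyodeoxycholic acid"),                                # HDCA
    c("isohyodeoxycholic acid"),                             # isoHDCA
    c("murideoxycholic acid"),                               # MDCA
    c("ursocholic acid"),                                    # UCA
    c("dehydrolithocholic acid"),                            # DHLCA
    c("dehydrocholic acid"),                                 # DHCA
    c("3-dehydrocholic acid"),                               # 3-DHCA
    c("12-dehydrocholic acid"),                              # 12-DHCA
    c("3-epideoxycholic acid"),                              # 3-epiDCA
    c("6-ketolithocholic acid", "6-ketoLDA"),                # 6-ketoLCA
    c("7-ketolithocholic acid"),                             # 7-ketoLCA
    c("12-ketolithocholic acid"),                            # 12-ketoLCA
    c("7-ketodeoxycholic acid"),                             # 7-ketoDCA
    c("7,12-diketolithocholic acid"),                        # 7,12-diketoLCA
    c("6,7-diketolithocholic acid"),                         # 6,7-diketoLCA
    c("3b-CA", "3beta-CA"),                                  # 3β-CA
    c("omega-MCA", "omega-muricholic acid",
      paste0(.OMEGA, "-muricholic acid")),                   # ω-MCA
    c("alpha-MCA", "alpha-muricholic acid",
      paste0(.ALPHA, "-muricholic acid")),                   # α-MCA
    c("beta-MCA", "beta-muricholic acid",
      paste0(.BETA, "-muricholic acid")),                    # β-MCA
    c("taurochenodeoxycholic acid"),                         # TCDCA
    c("taurocholic acid"),                                   # TCA
    c("glycocholic acid"),                                   # GCA
    c("glycohyocholic acid"),                                # GlyHCA
    character(0),                                            # CDCA-3-sulfate
    c("glycocholic acid-3-sulfate"),                         # GCA-3-sulfate
    character(0),                                            # UDCA-3-sulfate
    c("glycolithocholic acid-3-sulfate"),                    # GlyLCA-3-sulfate
    c("glycodehydrocholic acid")                             # GlyDHCA
  )
  names(syn) <- c(
    "CA", "alloCA", "CDCA", "DCA", "LCA", "isoLCA", "UDCA", "isoUDCA",
    "HCA", "HDCA", "isoHDCA", "MDCA", "UCA", "DHLCA", "DHCA", "3-DHCA",
    "12-DHCA", "3-epiDCA", "6-ketoLCA", "7-ketoLCA", "12-ketoLCA",
    "7-ketoDCA", "7,12-diketoLCA", "6,7-diketoLCA",
    paste0("3", .BETA, "-CA"), paste0(.OMEGA, "-MCA"),
    paste0(.ALPHA, "-MCA"), paste0(.BETA, "-MCA"),
    "TCDCA", "TCA", "GCA", "GlyHCA", "CDCA-3-sulfate", "GCA-3-sulfate",
    "UDCA-3-sulfate", "GlyLCA-3-sulfate", "GlyDHCA"
  )
  syn
}

.ba_lookup <- function() {
  syn <- .ba_synonyms()
  canon <- names(syn)
  keys <- tolower(canon)
  vals <- canon
  for (i in seq_along(syn)) {
    if (length(syn[[i]])) {
      keys <- c(keys, tolower(syn[[i]]))
      vals <- c(vals, rep(canon[i], length(syn[[i]])))
    }
  }
  stats::setNames(vals, keys)
}

#' Normalize a bile-acid name to its canonical identifier
#'
#' Matching is case-insensitive after whitespace collapse; when a long-form
#' name carries a parenthetical abbreviation, e.g. "isolithocholic acid
#' (isoLCA)", the abbreviation wins. Greek letters are preserved; the ASCII
#' spellings "omega-"/"alpha-"/"beta-" are accepted as aliases. Unrecognised
#' names are returned with whitespace collapsed, so novel compounds pass
#' through unchanged.
#'
#' @param raw character vector of bile-acid names.
#' @return character vector of canonical ids, same length as `raw`.
#' @examples
#' normalize_ba_name("isolithocholic acid (isoLCA)")
#' normalize_ba_name(c("HDCA", "omega-MCA"))
#' @export
normalize_ba_name <- function(raw) {
  if (!is.character(raw)) raw <- as.character(raw)
  if (length(raw) == 0L) return(character(0))
  if (any(!nzchar(trimws(raw)))) stop("empty bile-acid name")
  lookup <- .ba_lookup()
  vapply(raw, function(x) {
    x <- gsub("\\s+", " ", trimws(x))
    # parenthetical abbreviation: "long name (ABBR)"
    m <- regmatches(x, regexec("^(.*)\\(([^()]+)\\)\\s*$", x))[[1]]
    if (length(m) == 3) {
      ab <- trimws(m[3])
      hit <- lookup[tolower(ab)]
      if (!is.na(hit)) return(unname(hit))
      x <- ab
    }
    hit <- lookup[tolower(x)]
    if (!is.na(hit)) unname(hit) else x
  }, character(1), USE.NAMES = FALSE)
}

#' Transliterate canonical BA names to ASCII
#'
#' @param names character vector of canonical BA ids.
#' @return names with Greek omega/alpha/beta spelled out.
#' @export
ba_name_ascii <- function(names) {
  x <- gsub(.OMEGA, "omega", names)
  x <- gsub(.ALPHA, "alpha", x)
  gsub(.BETA, "beta", x)
}

#' Default primary/secondary/unclassified bile-acid classification scheme
#'
#' Primary BAs originate directly from the liver; secondary BAs are formed
#' through microbial transformation; a small set of oxo/dehydro species is
#' deliberately left unclassified. The three sets are pairwise disjoint.
#'
#' @return list with character vectors `primary`, `secondary`, `unclassified`.
#' @export
ba_class_scheme <- function() {
  scheme <- list(
    primary = c("CDCA", paste0("3", .BETA, "-CA"), paste0(.OMEGA, "-MCA"),
                paste0(.ALPHA, "-MCA"), paste0(.BETA, "-MCA"), "HCA", "CA",
                "CDCA-3-sulfate", "GCA-3-sulfate"),
    secondary = c("isoLCA", "LCA", "7-ketoLCA", "12-ketoLCA", "MDCA",
                  "isoUDCA", "isoHDCA", "UDCA", "HDCA", "3-epiDCA", "DCA",
                  "7,12-diketoLCA", "6,7-diketoLCA", "7-ketoDCA", "alloCA",
                  "UDCA-3-sulfate", "GlyLCA-3-sulfate"),
    unclassified = c("DHLCA", "6-ketoLCA", "DHCA", "12-DHCA", "3-DHCA",
                     "UCA", "GlyDHCA")
  )
  stopifnot(!anyDuplicated(unlist(scheme)))
  scheme
}

#' The 15 mutually increased bile acids (in vitro and in vivo)
#'
#' The bile acids significantly increased in both the in-vitro fermentation
#' and the in-vivo feeding comparison; the node set of the proposed
#' biotransformation pathway.
#'
#' @return character vector of 15 canonical ids.
#' @export
mutual_differential_bas <- function() {
  normalize_ba_name(c(
    "UDCA", "6-ketoLCA", "HDCA", "HCA", "3-DHCA", "3beta-CA", "alloCA",
    "LCA", "UCA", "MDCA", "omega-MCA", "isoHDCA", "isoLCA", "CDCA", "DHLCA"
  ))
}

#' The six exogenously supplemented bile acids
#'
#' Composition of the swine-derived supplement: HCA, CDCA, CA, HDCA and the
#' two conjugates TCDCA and TCA.
#'
#' @return character vector of 6 canonical ids.
#' @export
exogenous_bas <- function() c("HCA", "CDCA", "CA", "HDCA", "TCDCA", "TCA")
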