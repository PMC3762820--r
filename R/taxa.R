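#' Taxon groups used for both survey eras
#'
#' The 24 genus-level groups into which all tree records are binned. Colonial
#' surveyors rarely distinguished species within a genus, so modern inventory
#' species are collapsed to the same vocabulary before any comparison.
#'
#' @return Character vector of 24 taxon group codes, in canonical order.
#' @export
taxon_codes <- function() {
  c("ASHES", "BASSWOOD", "BEECH", "BIRCHES", "BLACKGUM", "CEDAR", "CHERRIES",
    "CHESTNUT", "CYPRESS", "ELMS", "FIR", "HEMLOCK", "HICKORIES", "HORNBEAM",
    "MAGNOLIAS", "MAPLE", "OAK", "PINES", "POPLARS", "SPRUCES", "SYCAMORE",
    "TAMARACK", "TULIP", "WALNUTS")
}

#' Sentinel code for names that cannot be binned
#' @export
UNBINNED <- "UNBINNED"

# Genus -> group. Keyed on the lower-cased first word of a Latin binomial,
# plus common colloquial names the colonial surveys used.
.genus_map <- c(
  fraxinus = "ASHES",      ash = "ASHES",        ashes = "ASHES",
  tilia = "BASSWOOD",      basswood = "BASSWOOD", linden = "BASSWOOD",
  fagus = "BEECH",         beech = "BEECH",
  betula = "BIRCHES",      birch = "BIRCHES",    birches = "BIRCHES",
  nyssa = "BLACKGUM",      blackgum = "BLACKGUM", tupelo = "BLACKGUM",
  thuja = "CEDAR",         juniperus = "CEDAR",  chamaecyparis = "CEDAR",
  cedar = "CEDAR",
  prunus = "CHERRIES",     cherry = "CHERRIES",  cherries = "CHERRIES",
  castanea = "CHESTNUT",   chestnut = "CHESTNUT",
  taxodium = "CYPRESS",    cypress = "CYPRESS",
  ulmus = "ELMS",          elm = "ELMS",         elms = "ELMS",
  abies = "FIR",           fir = "FIR",
  tsuga = "HEMLOCK",       hemlock = "HEMLOCK",
  carya = "HICKORIES",     hickory = "HICKORIES", hickories = "HICKORIES",
  ostrya = "HORNBEAM",     carpinus = "HORNBEAM", hornbeam = "HORNBEAM",
  ironwood = "HORNBEAM",
  magnolia = "MAGNOLIAS",  magnolias = "MAGNOLIAS",
  acer = "MAPLE",          maple = "MAPLE",      maples = "MAPLE",
  quercus = "OAK",         oak = "OAK",          oaks = "OAK",
  pinus = "PINES",         pine = "PINES",       pines = "PINES",
  populus = "POPLARS",     poplar = "POPLARS",   poplars = "POPLARS",
  aspen = "POPLARS",
  picea = "SPRUCES",       spruce = "SPRUCES",   spruces = "SPRUCES",
  platanus = "SYCAMORE",   sycamore = "SYCAMORE", buttonwood = "SYCAMORE",
  larix = "TAMARACK",      tamarack = "TAMARACK", larch = "TAMARACK",
  liriodendron = "TULIP",  tulip = "TULIP",
  juglans = "WALNUTS",     walnut = "WALNUTS",   walnuts = "WALNUTS"
)

#' Default raw-name mapping
#'
#' Maps free-text tree names (Latin binomials, genera, or colonial colloquial
#' names) to taxon group codes. Matching is case- and whitespace-insensitive;
#' a full-name lookup is tried first, then the first word (the genus).
#'
#' @return Named character vector: normalized raw name -> taxon group code.
#' @export
default_name_map <- function() .genus_map

.normalize_name <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

#' Bin raw tree names into taxon groups
#'
#' @param raw_name Character vector of free-text names.
#' @param name_map Named vector mapping normalized names to group codes.
#' @return Character vector of taxon codes; unknown names get `UNBINNED`.
#'   Records flagged `UNBINNED` are excluded (with a logged count) by
#'   downstream composition builders rather than silently dropped.
#' @examples
#' bin_taxon(c("Acer rubrum", "Castanea dentata", "Ailanthus altissima"))
#' @export
bin_taxon <- function(raw_name, name_map = default_name_map()) {
  if (length(raw_name) == 0L) return(character(0))
  nm <- .normalize_name(raw_name)
  code <- unname(name_map[nm])
  miss <- is.na(code)
  if (any(miss)) {
    genus <- sub(" .*$", "", nm[miss])
    code[miss] <- unname(name_map[genus])
  }
  code[is.na(code)] <- UNBINNED
  bad <- !(code %in% c(taxon_codes(), UNBINNED))
  if (any(bad)) stop("name_map maps to unknown taxon codes: ",
                     paste(unique(code[bad]), collapse = ", "))
  code
}

#' Add a taxon_code column to a tree table
#'
#' @param trees Data frame with a `raw_name` column.
#' @param name_map See [bin_taxon()].
#' @return `trees` with a `taxon_code` column; a message reports how many
#'   records could not be binned.
#' @export
bin_trees <- function(trees, name_map = default_name_map()) {
  stopifnot(is.data.frame(trees), "raw_name" %in% names(trees))
  trees$taxon_code <- bin_taxon(trees$raw_name, name_map)
  n_un <- sum(trees$taxon_code == UNBINNED)
  if (n_un > 0L)
    message(n_un, " tree record(s) could not be binned and are flagged UNBINNED")
  trees
}
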