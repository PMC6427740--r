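#' Construct a contaminant-indicator schema
#'
#' @param foods character vector of unique food names.
#' @param contaminants character vector of unique contaminant names.
#' @return a [ContaminantSchema-class].
#' @examples
#' sc <- ContaminantSchema(c("rice", "pork"), c("Pb", "Cd", "Hg"))
#' nIndicators(sc)        # 6
#' columnId(sc, "pork", "Cd")
#' @export
ContaminantSchema <- function(foods, contaminants) {
  new("ContaminantSchema", foods = as.character(foods),
      contaminants = as.character(contaminants))
}

#' @rdname ContaminantSchema-class
#' @export
setMethod("foods", "ContaminantSchema", function(x) x@foods)

#' @rdname ContaminantSchema-class
#' @export
setMethod("contaminants", "ContaminantSchema", function(x) x@contaminants)

#' @rdname ContaminantSchema-class
#' @export
setMethod("nIndicators", "ContaminantSchema",
          function(x) length(x@foods) * length(x@contaminants))

setMethod("show", "ContaminantSchema", function(object) {
  cat("ContaminantSchema:", length(object@foods), "foods x",
      length(object@contaminants), "contaminants =",
      nIndicators(object), "indicator columns\n")
})

#' Map (food, contaminant) pairs to column ids and back
#'
#' Column ids are 1-based and food-major: the pair (food i, contaminant j)
#' occupies column (i - 1) * |contaminants| + j. The mapping is a bijection.
#'
#' @param schema a [ContaminantSchema-class].
#' @param food,contaminant names (vectorized).
#' @return `columnId`: integer ids; `columnPair`: data.frame with columns
#'   `food` and `contaminant`.
#' @export
columnId <- function(schema, food, contaminant) {
  fi <- match(food, schema@foods)
  ci <- match(contaminant, schema@contaminants)
  if (anyNA(fi)) stop("unknown food name(s): ",
                      paste(unique(food[is.na(fi)]), collapse = ", "))
  if (anyNA(ci)) stop("unknown contaminant name(s): ",
                      paste(unique(contaminant[is.na(ci)]), collapse = ", "))
  (fi - 1L) * length(schema@contaminants) + ci
}

#' @rdname columnId
#' @param id integer column ids in 1..nIndicators(schema).
#' @export
columnPair <- function(schema, id) {
  id <- as.integer(id)
  n <- nIndicators(schema)
  if (any(id < 1L | id > n)) stop("column id out of range 1..", n)
  nc <- length(schema@contaminants)
  data.frame(food = schema@foods[(id - 1L) %/% nc + 1L],
             contaminant = schema@contaminants[(id - 1L) %% nc + 1L],
             stringsAsFactors = FALSE)
}

## ---- full-scale study schema -------------------------------------------

## 119 food types in six classes. The published food table enumerates 118
## distinct items; one entry was lost in transcription of the source table,
## so a clearly-labelled synthetic placeholder restores the stated count.
.fullScaleFoods <- function() {
  cereals <- c("rice", "wheat", "barley", "corn", "millet", "black rice",
               "sticky rice")
  beans <- c("soybean", "mung soybean", "red bean", "black bean", "broad bean",
             "pea", "cow pea", "hyacinth bean", "kidney bean", "sword bead")
  vegetables <- c("cabbage", "pak choi cabbage", "baby cabbage",
    "celery cabbage", "celery", "lettuce", "broccoli", "Chinese broccoli",
    "mustard leaf", "leaf lettuce", "okra", "rape", "spinach", "water spinach",
    "potherb mustard", "amaranth", "cauliflower", "purslane", "yam", "carrot",
    "celtuce", "summer radish", "loofah", "tomato", "cucumbers", "lappa",
    "radish", "potato", "sweet potato", "pumpkin", "bitter gourd",
    "white gourd", "chilli pepper", "bell pepper", "green pepper",
    "sweet pepper", "pod pepper", "pea sprout", "soybean sprout",
    "mung bean sprout", "Chinese toon sprout", "shiitake", "button mushroom",
    "oyster mushroom", "needle mushroom", "agaric", "day lily", "tremella",
    "spring onion", "Chinese onion", "ginger", "caraway", "garlic",
    "fragrant-flowered garlic", "garlic sprouts")
  fruits <- c("apple", "gala apple", "bergamot pear", "snow pear", "mili pear",
    "pineapple", "orange", "navel orange", "vibrio mimicus", "pomelo", "peach",
    "nectarine", "melon", "watermelon", "Hami melon", "apricot", "plum",
    "cherry", "bayberry", "grape", "longan", "lychee", "winter jujube",
    "red jujube", "sugarcane", "pitaya")
  meatEggs <- c("pork", "beef", "mutton", "chicken", "duck", "egg", "duck egg",
                "quail egg")
  aquatic <- c("kelp", "laver", "carp", "grass carp", "yellow croaker",
               "perch", "crucian", "prawn", "river prawn", "crab",
               "river crab", "river snail")
  c(cereals, beans, vegetables, fruits, meatEggs, aquatic,
    "unlisted food (placeholder)")
}

## 227 contaminant types. Pesticides, herbicides and endocrine disruptors are
## published only as class counts (66 / 18 / 68) with named references, so
## they appear as numbered members of their class; the heavy-metal row lists
## Ni twice, and the second occurrence is disambiguated to keep names unique.
.fullScaleContaminants <- function() {
  heavyMetals <- c("Pb", "Cd", "Hg", "Cu", "Ni", "As", "Be", "Bi", "Sb", "Tl",
                   "Cr", "Mo", "Ni (2)", "Zn", "F", "V")
  inorganicOther <- c("cyanide", "nitrate", "nitrite", "sulfate", "carbonate")
  hydrocarbons <- c("benzene series", "polycyclic aromatic hydrocarbons",
                    "total petroleum hydrocarbon")
  halogenated <- c("hydrochlorofluorocarbons", "chlorinated solvents",
                   "polychlorinated biphenyls", "dioxin")
  oxygenated <- c("alcohols", "phenols", "ethers", "esters", "phthalate")
  dyes <- c("azo", "quaternary ammonium compounds", "benzidine",
            "naphthylamine")
  plastics <- c("polypropylene", "polyphenyl ether", "polystyrene",
                "phthalic acid esters")
  pesticides <- sprintf("pesticide %02d", 1:66)
  herbicides <- sprintf("herbicide %02d", 1:18)
  endocrine <- sprintf("endocrine disruptor %02d", 1:68)
  organicOther <- c("trichloroethylene", "organochlorine pesticide")
  bacteria <- c("salmonella", "shigella", "dysentery bacillus",
    "plague bacillus", "tubercle bacillus", "typhoid bacillus",
    "diphtheria bacillus", "Francisella tularensis", "Brucella",
    "vibrio parahaemolyticus", "vibrio cholerae", "vibrio mimicus",
    "vibrio fluvialis", "clostridium tetani", "clostridium botulinum",
    "clostridium perfringens", "staphylococcus aureus", "Bacillus anthraci",
    "Escherichia coli", "Yersinia", "helicobcter pylori",
    "campylobacter jejuni", "aeromonas hydrophila", "roundworm eggs",
    "hookworm eggs")
  fungi <- c("candida albicans", "aspergillus fumigatus", "mucor racemosus")
  virus <- c("rotavirus", "norovirus", "sapovirus", "astrovirus")
  c(heavyMetals, inorganicOther, hydrocarbons, halogenated, oxygenated, dyes,
    plastics, pesticides, herbicides, endocrine, organicOther, bacteria,
    fungi, virus)
}

#' Full-scale study schema and empty tuple grid
#'
#' Builds the schema at the scale of the original ten-city surveillance
#' study: 119 food types crossed with 227 contaminant types (27,013
#' indicator columns) and an empty grid of 10 regions x 178 weeks
#' (1,780 region-week tuple slots).
#'
#' @return a list with elements `schema` (a [ContaminantSchema-class]) and
#'   `grid` (data.frame with columns `region_id` and `week` listing every
#'   tuple slot).
#' @examples
#' fs <- fullScaleSchema()
#' nIndicators(fs$schema)   # 27013
#' nrow(fs$grid)            # 1780
#' @export
fullScaleSchema <- function() {
  schema <- ContaminantSchema(.fullScaleFoods(), .fullScaleContaminants())
  regions <- sprintf("region%02d", 1:10)
  grid <- expand.grid(week = 0:177, region_id = regions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("region_id", "week")]
  grid <- grid[order(grid$region_id, grid$week), ]
  rownames(grid) <- NULL
  list(schema = schema, grid = grid)
}
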