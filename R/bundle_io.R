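# Bundle serialisation: one CSV per schedule plus a JSON manifest, so a
# bundle can be inspected, edited and reloaded without the generator.

BUNDLE_TABLES <- c("demography", "bmi", "disease_rates", "diseases", "rr",
                   "unrelated_cost")

#' Write a parameter bundle to a directory of CSV files
#'
#' @param bundle A `pmslt_bundle`.
#' @param dir Directory to create/populate; one CSV per schedule plus
#'   `manifest.json` carrying the metadata.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tb in BUNDLE_TABLES) {
    write.csv(bundle[[tb]], file.path(dir, paste0(tb, ".csv")),
              row.names = FALSE)
  }
  jsonlite::write_json(bundle$meta, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a parameter bundle from a directory written by [write_bundle()]
#'
#' Validates on read and stops with the list of violations if the bundle on
#' disk is inconsistent.
#'
#' @param dir Directory containing the schedule CSVs and `manifest.json`.
#' @return A `pmslt_bundle`.
#' @export
read_bundle <- function(dir) {
  man <- file.path(dir, "manifest.json")
  if (!file.exists(man)) stop("read_bundle: no manifest.json in ", dir)
  bundle <- lapply(setNames(BUNDLE_TABLES, BUNDLE_TABLES), function(tb) {
    f <- file.path(dir, paste0(tb, ".csv"))
    if (!file.exists(f)) stop("read_bundle: missing ", basename(f))
    read.csv(f, stringsAsFactors = FALSE)
  })
  bundle$meta <- jsonlite::read_json(man, simplifyVector = TRUE)
  class(bundle) <- "pmslt_bundle"
  v <- validate_bundle(bundle)
  if (length(v)) {
    stop("read_bundle: bundle fails validation:\n  ",
         paste(utils::head(v, 10), collapse = "\n  "))
  }
  bundle
}
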