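#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## canonical cell status vocabulary
.statuses <- c("valid", "below_LOD", "below_LLOQ", "semi_quant",
               "imputed", "missing")

## well role vocabulary; calibrators carry their level as "calibrator_<l>"
.fixed_roles <- c("study", "SPQC", "kit_QC1", "kit_QC2", "kit_QC3",
                  "blank", "zero", "NIST", "reference_serum")

is_valid_role <- function(role) {
  role %in% .fixed_roles | grepl("^calibrator_[0-9]+$", role)
}

stop2 <- function(...) stop(..., call. = FALSE)

## deterministic md5 of an R config object via canonical (name-sorted) JSON
canonical_json <- function(x) {
  sort_rec <- function(v) {
    if (is.list(v) && !is.null(names(v)) && length(v)) {
      v <- v[order(names(v))]
      lapply(v, sort_rec)
    } else if (is.list(v)) lapply(v, sort_rec) else v
  }
  jsonlite::toJSON(sort_rec(x), auto_unbox = TRUE, digits = NA,
                   null = "null", na = "null")
}

config_hash <- function(config) {
  if (is.null(config)) return("none")
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f), add = TRUE)
  writeLines(as.character(canonical_json(unclass(config))), f)
  unname(tools::md5sum(f))
}

## full-precision number formatting so CSV round trips are bit-exact
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}
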