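#' Read a component property table
#'
#' Expects a CSV with header
#' `id,name,MW,AlogP,nHdon,nHacc,TPSA,RBN,OB,Caco2,DL,GI`. An empty RBN
#' cell means the rotatable-bond count was not tabulated; the Lipinski
#' sub-condition on RBN is then skipped for that row.
#'
#' @param path path to the CSV file.
#' @return data.frame of component records, validated.
#' @export
read_components <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "name", "MW", "AlogP", "nHdon", "nHacc", "OB",
                "Caco2", "DL", "GI")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_domain("component table is missing columns: ",
                paste(missing, collapse = ", "))
  }
  if (!"RBN" %in% names(df)) df$RBN <- NA_real_
  if (!"TPSA" %in% names(df)) df$TPSA <- NA_real_
  validate_components(df)
  df
}

validate_components <- function(df) {
  if (any(duplicated(df$id))) stop_domain("duplicate component ids")
  if (any(!is.finite(df$MW)) || any(df$MW <= 0)) {
    stop_domain("MW must be finite and > 0")
  }
  for (col in c("nHdon", "nHacc")) {
    v <- df[[col]]
    if (any(!is.finite(v)) || any(v < 0) || any(v != round(v))) {
      stop_domain(col, " must be non-negative integers")
    }
  }
  if (any(is.finite(df$RBN) & (df$RBN < 0 | df$RBN != round(df$RBN)))) {
    stop_domain("RBN must be non-negative integers when present")
  }
  if (any(df$DL < 0 | df$DL > 1)) stop_domain("DL must lie in [0, 1]")
  gi <- toupper(trimws(df$GI))
  if (!all(gi %in% c("HIGH", "LOW"))) {
    stop_domain("GI class must be High or Low")
  }
  invisible(df)
}

#' Lipinski's rule of five
#'
#' Counts violations among MW <= 500, AlogP <= 5, H-bond donors <= 5,
#' H-bond acceptors <= 10 and rotatable bonds <= 10. The RBN condition is
#' skipped (with a one-time warning) for rows where RBN is missing, as in
#' property tables that do not report it. A compound passes when its
#' violation count does not exceed `max_violations`; the conventional
#' reading of the rule tolerates one violation.
#'
#' @param records data.frame with columns MW, AlogP, nHdon, nHacc and
#'   optionally RBN (NA allowed).
#' @param max_violations maximum violations tolerated (default 1).
#' @return data.frame with integer column `violations` and logical `pass`.
#' @export
#' @examples
#' lipinski_check(data.frame(MW = 286.25, AlogP = 1.77, nHdon = 4, nHacc = 6))
lipinski_check <- function(records, max_violations = 1) {
  stopifnot(is.data.frame(records), max_violations >= 0)
  if (!"RBN" %in% names(records)) records$RBN <- NA_real_
  if (any(records$nHdon < 0) || any(records$nHacc < 0)) {
    stop_domain("hydrogen-bond counts must be non-negative")
  }
  v <- (records$MW > 500) + (records$AlogP > 5) +
    (records$nHdon > 5) + (records$nHacc > 10)
  has_rbn <- is.finite(records$RBN)
  if (any(!has_rbn)) {
    warning("RBN missing for ", sum(!has_rbn),
            " component(s); rotatable-bond condition skipped", call. = FALSE)
  }
  v <- v + ifelse(has_rbn & records$RBN > 10, 1L, 0L)
  data.frame(violations = as.integer(v), pass = v <= max_violations)
}

#' Tanimoto drug-likeness coefficient
#'
#' Continuous Tanimoto similarity between two descriptor vectors,
#' `T = (A.B) / (|A|^2 + |B|^2 - A.B)`. In database-dependent
#' drug-likeness scoring, `a` holds a compound's molecular descriptors and
#' `b` the average descriptor vector of a reference drug library, so the
#' score measures how close the compound sits to an "average drug".
#' For non-negative vectors the score lies in [0, 1]; identical vectors
#' score exactly 1.
#'
#' @param a,b numeric vectors of equal length with finite entries.
#' @return scalar similarity score.
#' @export
#' @examples
#' tanimoto_dl(c(1, 0), c(1, 1))  # 0.5
tanimoto_dl <- function(a, b) {
  if (length(a) != length(b)) stop_domain("descriptor vectors differ in length")
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop_domain("descriptor vectors must be finite")
  }
  ab <- sum(a * b)
  denom <- sum(a * a) + sum(b * b) - ab
  if (denom == 0) stop_domain("Tanimoto undefined: both vectors are zero")
  ab / denom
}

#' Default ADME screening thresholds
#'
#' Oral bioavailability OB >= 30 (percent), Caco-2 permeability > -0.4
#' (log nm/s; compounds below are considered non-permeable), drug-likeness
#' DL >= 0.18, gastrointestinal absorption class High, and Lipinski's rule
#' with at most one violation. OB and DL are inclusive bounds; Caco-2 is
#' strict, mirroring the inequalities the thresholds are conventionally
#' quoted with.
#'
#' @param ob,caco2,dl numeric thresholds.
#' @param gi required GI class (case-insensitive).
#' @param max_lipinski_violations tolerated Lipinski violations.
#' @return named list of thresholds.
#' @export
adme_thresholds <- function(ob = 30, caco2 = -0.4, dl = 0.18, gi = "High",
                            max_lipinski_violations = 1) {
  list(ob = ob, caco2 = caco2, dl = dl, gi = gi,
       max_lipinski_violations = max_lipinski_violations)
}

#' ADME screening of herb components
#'
#' Applies the five screening criteria (OB, Caco-2, DL, GI class,
#' Lipinski) to a component property table. A component passes strictly
#' when all five flags hold. Components on the whitelist are retained even
#' when they fail — the add-back mechanism for compounds kept on
#' independent pharmacological evidence despite poor predicted
#' pharmacokinetics.
#'
#' @param records component data.frame (see [read_components()]).
#' @param thresholds list from [adme_thresholds()].
#' @param whitelist character vector of component ids to retain regardless
#'   of the strict filter. Unknown ids trigger a warning, not an error.
#' @return data.frame (class `screen_report`) with one row per component:
#'   per-criterion logical flags, `strict_pass`, `retained` and
#'   `retained_via_whitelist`, plus a `failed_criteria` summary string.
#' @export
#' @examples
#' tbl <- read_components(system.file("extdata", "hr_components.csv",
#'                                    package = "netpharm"))
#' rep <- adme_screen(tbl)
#' tbl$name[rep$strict_pass]
adme_screen <- function(records, thresholds = adme_thresholds(),
                        whitelist = character()) {
  validate_components(records)
  unknown <- setdiff(whitelist, records$id)
  if (length(unknown)) {
    warning("whitelist ids not in table: ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }
  lip <- suppressWarnings(
    lipinski_check(records, thresholds$max_lipinski_violations)
  )
  flags <- data.frame(
    id = records$id,
    flag_OB = records$OB >= thresholds$ob,
    flag_Caco2 = records$Caco2 > thresholds$caco2,
    flag_DL = records$DL >= thresholds$dl,
    flag_GI = toupper(trimws(records$GI)) == toupper(thresholds$gi),
    flag_Lipinski = lip$pass,
    lipinski_violations = lip$violations,
    stringsAsFactors = FALSE
  )
  crit <- c("flag_OB", "flag_Caco2", "flag_DL", "flag_GI", "flag_Lipinski")
  flags$strict_pass <- Reduce(`&`, flags[crit])
  flags$retained_via_whitelist <- !flags$strict_pass & flags$id %in% whitelist
  flags$retained <- flags$strict_pass | flags$retained_via_whitelist
  lab <- sub("^flag_", "", crit)
  flags$failed_criteria <- apply(!as.matrix(flags[crit]), 1, function(f) {
    paste(lab[f], collapse = ";")
  })
  class(flags) <- c("screen_report", class(flags))
  flags
}

#' Write a screening report
#'
#' Writes the per-component flag table as CSV and a JSON summary with the
#' strict-pass, whitelist and retained counts.
#'
#' @param report result of [adme_screen()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_screen_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "screen_report.csv")
  utils::write.csv(as.data.frame(report), csv, row.names = FALSE)
  js <- file.path(dir, "screen_summary.json")
  jsonlite::write_json(
    list(n_components = nrow(report),
         n_strict_pass = sum(report$strict_pass),
         n_whitelist_addback = sum(report$retained_via_whitelist),
         n_retained = sum(report$retained),
         retained_ids = report$id[report$retained]),
    js, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(c(csv, js))
}
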