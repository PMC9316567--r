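## Per-cell measurement tables: schema, validation, CSV I/O, configuration.

CELL_TABLE_COLUMNS <- c("cell_id", "experiment_id", "role",
                        "green_raw", "red_raw", "area", "perimeter",
                        "f5mc", "fpi")

CLASSIFIED_COLUMNS <- c(CELL_TABLE_COLUMNS,
                        "green_norm", "red_norm", "circularity",
                        "group", "eu", "eu_domain", "cnf", "cnf_norm")

#' Validate a per-cell measurement table
#'
#' Checks the invariants every downstream stage relies on: positive area and
#' perimeter, non-negative fluorescence, a recognised culture role, paired
#' nuclear channels (`f5mc` present implies `fpi` present and positive), and
#' the isoperimetric constraint `perimeter^2 >= 4*pi*area - eps` that any
#' genuine planar outline satisfies up to digitization error.
#'
#' @param cells data.frame with the columns of [read_cell_table()].
#' @param iso_tol relative tolerance on the isoperimetric inequality,
#'   allowing for perimeter digitization on small regions.
#' @return `cells`, invisibly, with `role` as character; stops with
#'   row-indexed diagnostics on any violation.
#' @export
validate_cells <- function(cells, iso_tol = 0.15) {
  required <- setdiff(CELL_TABLE_COLUMNS, c("f5mc", "fpi"))
  missing <- setdiff(required, names(cells))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  for (col in c("green_raw", "red_raw", "area", "perimeter"))
    if (!is.numeric(cells[[col]]))
      stop("column '", col, "' is not numeric")
  cells$role <- as.character(cells$role)

  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx))
      stop(what, " in row(s): ", paste(utils::head(idx, 10), collapse = ", "),
           if (length(idx) > 10) " ..." else "")
  }
  bad(!(cells$role %in% CELL_ROLES),
      paste0("role not one of {", paste(CELL_ROLES, collapse = ", "), "}"))
  bad(is.na(cells$area) | cells$area <= 0, "non-positive or missing area")
  bad(is.na(cells$perimeter) | cells$perimeter <= 0,
      "non-positive or missing perimeter")
  bad(is.na(cells$green_raw) | cells$green_raw < 0, "negative green_raw")
  bad(is.na(cells$red_raw) | cells$red_raw < 0, "negative red_raw")
  if (!is.null(cells$f5mc)) {
    has5 <- !is.na(cells$f5mc)
    if (is.null(cells$fpi)) cells$fpi <- NA_real_
    bad(has5 & (is.na(cells$fpi) | cells$fpi <= 0),
        "f5mc present without positive fpi")
  }
  bad(cells$perimeter^2 < 4 * pi * cells$area * (1 - iso_tol),
      "perimeter^2 < 4*pi*area (impossible outline)")
  invisible(cells)
}

#' Read a per-cell measurement table from CSV
#'
#' The expected header is
#' `cell_id,experiment_id,role,green_raw,red_raw,area,perimeter,f5mc,fpi`;
#' the last two columns are optional and may be empty. `role` must be one of
#' `control_green`, `control_red`, `cocultured`. Rows violating the record
#' invariants abort with a diagnostic naming the offending rows.
#'
#' @param path CSV file path.
#' @return data.frame of validated cell records.
#' @seealso [write_cell_table()], [validate_cells()]
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cells <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"f5mc" %in% names(cells)) cells$f5mc <- NA_real_
  if (!"fpi" %in% names(cells)) cells$fpi <- NA_real_
  cells$f5mc <- as.numeric(cells$f5mc)
  cells$fpi <- as.numeric(cells$fpi)
  validate_cells(cells)
  cells[CELL_TABLE_COLUMNS]
}

#' Write a per-cell measurement table to CSV
#'
#' Writes the fixed column set of [read_cell_table()]; a read-back of the
#' file reproduces the input records (full double precision is retained).
#'
#' @param cells validated data.frame of cell records.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  cells <- as.data.frame(validate_cells(cells))
  for (col in setdiff(CELL_TABLE_COLUMNS, names(cells)))
    cells[[col]] <- NA_real_
  utils::write.csv(cells[CELL_TABLE_COLUMNS], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Write a classified cell table
#'
#' Output schema of the analysis stage: the input columns plus
#' `green_norm,red_norm,circularity,group,eu,eu_domain,cnf,cnf_norm`.
#'
#' @param cells classified data.frame (e.g. the `cells` component of a
#'   [cartesian_transfer()] fit).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_classified_table <- function(cells, path) {
  for (col in setdiff(CLASSIFIED_COLUMNS, names(cells)))
    cells[[col]] <- NA
  out <- cells[CLASSIFIED_COLUMNS]
  out$group <- as.character(out$group)
  out$eu_domain <- as.character(out$eu_domain)
  # domain labels contain commas; character fields must be quoted
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a classified cell table
#'
#' @param path CSV written by [write_classified_table()].
#' @return data.frame with `group` and `eu_domain` restored as factors with
#'   the canonical level order.
#' @export
read_classified_table <- function(path) {
  cells <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("group" %in% names(cells))
    cells$group <- factor(cells$group, levels = CARTESIAN_GROUPS)
  if ("eu_domain" %in% names(cells))
    cells$eu_domain <- factor(cells$eu_domain, levels = EU_DOMAINS)
  cells
}

## ---- configuration ----------------------------------------------------

default_config <- function() {
  list(
    orientation = "standard",   # "flipped" negates EU and mirrors groups
    trim = 0,                   # fraction of control cells trimmed per tail
    background_mode = "cross",  # "cross" or "rates" (explicit values below)
    background_rates = NULL,    # list(green = , red = ) when mode = "rates"
    max_controls = 100,         # control cells sampled per population
    max_cocultured = 1000,      # co-cultured cells included in the analysis
    seed = 1,
    min_size = 20,              # smallest segmented object, pixels
    threshold = "otsu",         # or list(green = , red = ) manual values
    split_touching = FALSE,
    channels = list(green = 1, red = 2, pi = 3, mc5 = 4),
    out_dir = "cocultr-out",
    synthetic = list()          # overrides for synthetic_config()
  )
}

#' Load an analysis configuration
#'
#' Reads a YAML key-value file, fills unset keys with package defaults and
#' warns on unknown keys. The defaults encode the study conditions: 100
#' control cells per population and up to 1000 co-cultured cells enter the
#' analysis (seeded uniform subsampling when inputs exceed the caps),
#' control ranges are untrimmed (`trim = 0`), background is estimated
#' cross-channel from the control populations.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return named list of configuration values.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      warning("unknown config key(s) ignored: ",
              paste(unknown, collapse = ", "))
    for (k in intersect(names(user), names(cfg))) cfg[[k]] <- user[[k]]
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (!cfg$orientation %in% c("standard", "flipped"))
    stop("orientation must be 'standard' or 'flipped'")
  if (!is.numeric(cfg$trim) || cfg$trim < 0 || cfg$trim >= 0.5)
    stop("trim must be in [0, 0.5)")
  if (!cfg$background_mode %in% c("cross", "rates"))
    stop("background_mode must be 'cross' or 'rates'")
  if (cfg$background_mode == "rates" &&
      (is.null(cfg$background_rates$green) || is.null(cfg$background_rates$red)))
    stop("background_mode 'rates' requires background_rates$green and $red")
  if (cfg$max_controls < 1 || cfg$max_cocultured < 1)
    stop("sampling caps must be positive")
  cfg
}

# seeded uniform subsample to at most `cap` rows, order preserved
cap_sample <- function(cells, cap, seed) {
  n <- nrow(cells)
  if (n <= cap) return(cells)
  idx <- withr_seed(seed, sample.int(n, cap))
  cells[sort(idx), , drop = FALSE]
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
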