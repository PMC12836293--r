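# Interchange formats: dose grids as raw float32 + JSON header, structure
# masks as run-length-encoded JSON, plans as a documented JSON schema,
# delivery logs as CSV (one row per control point per leaf/axis), DVHs as
# CSV. All round-trip tested.

#' Write / read a dose grid (raw + JSON header)
#'
#' `<prefix>.raw` holds little-endian float32 values (x fastest);
#' `<prefix>.json` holds shape, spacing, origin, frame and dtype.
#'
#' @param dose a [dose_grid()].
#' @param prefix path prefix (without extension).
#' @return `write_dose_grid` the prefix, invisibly; `read_dose_grid` a
#'   [dose_grid()].
#' @export
write_dose_grid <- function(dose, prefix) {
  header <- list(shape = dim(dose$values), spacing_mm = dose$spacing_mm,
                 origin_mm = dose$origin_mm, frame_id = dose$frame_id,
                 dtype = "float32", byte_order = "little")
  jsonlite::write_json(header, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(prefix, ".raw"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(dose$values), con, size = 4, endian = "little")
  invisible(prefix)
}

#' @rdname write_dose_grid
#' @export
read_dose_grid <- function(prefix) {
  h <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  n <- prod(h$shape)
  con <- file(paste0(prefix, ".raw"), "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  dose_grid(array(pmax(v, 0), dim = h$shape), h$spacing_mm, h$origin_mm,
            h$frame_id)
}

#' Write / read a structure mask (run-length-encoded JSON)
#'
#' The mask is flattened in column-major order and stored as alternating
#' run lengths starting with a FALSE run.
#'
#' @param structure a [structure_mask()].
#' @param path JSON file path.
#' @export
write_structure_mask <- function(structure, path) {
  r <- rle(as.vector(structure$mask))
  if (r$values[1]) { r$lengths <- c(0L, r$lengths); r$values <- c(FALSE, r$values) }
  obj <- list(name = structure$name, shape = dim(structure$mask),
              spacing_mm = structure$spacing_mm,
              origin_mm = structure$origin_mm, frame_id = structure$frame_id,
              rle = r$lengths)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_structure_mask
#' @export
read_structure_mask <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals <- rep(rep(c(FALSE, TRUE), length.out = length(o$rle)), o$rle)
  structure_mask(o$name, array(vals, dim = o$shape), o$spacing_mm,
                 o$origin_mm, o$frame_id)
}

#' Write / read a beam plan (JSON schema)
#'
#' @param plan a [beam_plan()].
#' @param path JSON file path.
#' @export
write_beam_plan <- function(plan, path) {
  jsonlite::write_json(
    list(max_leaf_travel_mm = plan$max_leaf_travel_mm, beams = plan$beams),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_beam_plan
#' @export
read_beam_plan <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = FALSE)
  as_mat <- function(x)   # nested row-major arrays -> matrix
    matrix(unlist(x), nrow = length(x), byrow = TRUE)
  beams <- lapply(o$beams, function(b) {
    b$left <- as_mat(b$left)
    b$right <- as_mat(b$right)
    b$gantry_deg <- as.numeric(unlist(b$gantry_deg))
    b$cum_mu_frac <- as.numeric(unlist(b$cum_mu_frac))
    b$jaw_x <- as.numeric(unlist(b$jaw_x))
    b
  })
  beam_plan(beams, max_leaf_travel_mm = o$max_leaf_travel_mm)
}

#' Write / read a delivery log (CSV, one row per CP per leaf/axis)
#'
#' Columns: beam, cp, record (`left`/`right`/`gantry`), index (leaf pair,
#' or 0 for gantry), value.
#'
#' @param log a [delivery_log()].
#' @param path CSV file path.
#' @param plan the matching [beam_plan()] (needed to rebuild shapes).
#' @export
write_delivery_log <- function(log, path) {
  rows <- lapply(log$beams, function(b) {
    n_cp <- nrow(b$left); n_pairs <- ncol(b$left)
    rbind(
      data.frame(beam = b$id, cp = rep(seq_len(n_cp), n_pairs),
                 record = "left", index = rep(seq_len(n_pairs), each = n_cp),
                 value = as.vector(b$left)),
      data.frame(beam = b$id, cp = rep(seq_len(n_cp), n_pairs),
                 record = "right", index = rep(seq_len(n_pairs), each = n_cp),
                 value = as.vector(b$right)),
      data.frame(beam = b$id, cp = seq_len(n_cp), record = "gantry",
                 index = 0L, value = b$gantry_deg))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_delivery_log
#' @export
read_delivery_log <- function(path, plan) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  beams <- lapply(plan$beams, function(pb) {
    sub <- df[df$beam == pb$id, ]
    get_mat <- function(rec) {
      s <- sub[sub$record == rec, ]
      m <- matrix(NA_real_, nrow(pb$left), ncol(pb$left))
      m[cbind(s$cp, s$index)] <- s$value
      m
    }
    g <- sub[sub$record == "gantry", ]
    list(id = pb$id, left = get_mat("left"), right = get_mat("right"),
         gantry_deg = g$value[order(g$cp)])
  })
  delivery_log(plan, beams)
}

#' Export a gamma map in the raw+JSON interchange raster
#'
#' Points below the low-dose threshold (NA in the gamma map) are stored
#' as -1; the header records the criteria and pass rate.
#'
#' @param result a `gamma_result` from [gamma_index()].
#' @param prefix path prefix (without extension).
#' @export
write_gamma_map <- function(result, prefix) {
  g <- result$gamma
  g[is.na(g)] <- -1
  header <- list(shape = dim(g), dtype = "float32", byte_order = "little",
                 not_evaluated_value = -1, criteria = result$criteria,
                 pass_rate_percent = result$pass_rate_percent)
  jsonlite::write_json(header, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(prefix, ".raw"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(g), con, size = 4, endian = "little")
  invisible(prefix)
}

#' Export a cumulative DVH as CSV
#'
#' @param dvh a `dvh`.
#' @param path CSV path; columns `dose_Gy`, `volume_fraction`.
#' @export
write_dvh_csv <- function(dvh, path) {
  utils::write.csv(as.data.frame(dvh), path, row.names = FALSE)
  invisible(path)
}
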