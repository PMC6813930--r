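# Patient-state serialization: lossless, version-stamped JSON snapshots of
# the full coupled state (inflammation, drugs, physiology, infusion
# schedule). Doubles are written with 17 significant digits, which
# round-trips IEEE-754 exactly, so a resumed run reproduces an uninterrupted
# one bit for bit.

.SNAPSHOT_VERSION <- "sepsim-snapshot-1"

#' Patient snapshot
#'
#' Full coupled state at a point in simulation time: the 18 AIR states and
#' the TLR switch, per-drug compartment amounts, the complete physiological
#' state, the active infusion schedule and the cumulative administered
#' fluid.
#'
#' @param time Simulation time (h).
#' @param air Numeric length-18 AIR state.
#' @param R TLR switch (0/1).
#' @param drug_amounts Named list of length-2 compartment amounts.
#' @param physio `physio_state`.
#' @param infusions Infusion schedule data.frame.
#' @param cum_fluid_ml Cumulative administered fluid (mL).
#' @param scenario Originating scenario (kept in memory, not serialized).
#' @return List of class `patient_snapshot`.
#' @export
patient_snapshot <- function(time, air, R, drug_amounts, physio, infusions,
                             cum_fluid_ml, scenario = NULL) {
  out <- list(time = time, air = as.numeric(air), R = R,
              drug_amounts = drug_amounts, physio = physio,
              infusions = infusions, cum_fluid_ml = cum_fluid_ml,
              scenario = scenario)
  class(out) <- "patient_snapshot"
  out
}

#' @export
print.patient_snapshot <- function(x, ...) {
  cat(sprintf("Patient snapshot at t = %.2f h: P_T %.3g, P_B %.3g, R %d, MAP %.1f, BV %.2f L\n",
              x$time, x$air[1L], x$air[5L], as.integer(x$R),
              x$physio$hemo$MAP, x$physio$blood_volume))
  invisible(x)
}

.enc_num <- function(x) {
  vapply(as.numeric(x), function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
}

.dec_num <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  out[x == "NA"] <- NA_real_
  out
}

#' Save and load patient snapshots
#'
#' Lossless JSON round trip of every state variable (doubles serialized at
#' full precision), stamped with a format version and a payload checksum.
#' Loading rejects version mismatches and corrupted or truncated files.
#'
#' @param snapshot `patient_snapshot`.
#' @param path File path.
#' @return `load_snapshot()` returns the `patient_snapshot` (without the
#'   in-memory scenario); `save_snapshot()` returns `path` invisibly.
#' @export
save_snapshot <- function(snapshot, path) {
  stopifnot(inherits(snapshot, "patient_snapshot"))
  ph <- snapshot$physio
  payload <- list(
    time = .enc_num(snapshot$time),
    air = .enc_num(snapshot$air),
    R = .enc_num(snapshot$R),
    drug_names = names(snapshot$drug_amounts),
    drug_amounts = lapply(snapshot$drug_amounts, .enc_num),
    physio = list(
      time = .enc_num(ph$time),
      blood_volume = .enc_num(ph$blood_volume),
      alb_p = .enc_num(ph$alb_p),
      pair_names = ph$pairs$name,
      pairs = lapply(ph$pairs[setdiff(names(ph$pairs), "name")], .enc_num),
      endo_dmg = .enc_num(ph$endo_dmg),
      no_lag = .enc_num(ph$no_lag),
      hemo = lapply(ph$hemo, .enc_num),
      renal = lapply(ph$renal, .enc_num),
      cum = lapply(ph$cum, .enc_num)
    ),
    infusions = list(
      kind = snapshot$infusions$kind, name = snapshot$infusions$name,
      start = .enc_num(snapshot$infusions$start),
      end = .enc_num(snapshot$infusions$end),
      rate = .enc_num(snapshot$infusions$rate),
      alb_rate = .enc_num(snapshot$infusions$alb_rate)
    ),
    cum_fluid_ml = .enc_num(snapshot$cum_fluid_ml)
  )
  body <- as.character(jsonlite::toJSON(payload, auto_unbox = FALSE))
  doc <- list(version = .SNAPSHOT_VERSION,
              checksum = .payload_checksum(body), payload = payload)
  writeLines(jsonlite::toJSON(doc, auto_unbox = FALSE, pretty = TRUE),
             path)
  invisible(path)
}

.payload_checksum <- function(body) {
  v <- utf8ToInt(body)
  sprintf("%d-%d", length(v),
          sum(v * (seq_along(v) %% 997)) %% 2147483647)
}

#' @rdname save_snapshot
#' @export
load_snapshot <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("snapshot file is corrupted or truncated: ",
                         conditionMessage(e), call. = FALSE))
  if (!identical(as.character(doc$version), .SNAPSHOT_VERSION))
    stop("snapshot version mismatch: found '", doc$version, "', expected '",
         .SNAPSHOT_VERSION, "'", call. = FALSE)
  body <- as.character(jsonlite::toJSON(
    jsonlite::fromJSON(path, simplifyVector = TRUE)$payload,
    auto_unbox = FALSE))
  # recompute checksum from a canonical re-serialization of the payload
  pl <- doc$payload
  if (!identical(as.character(doc$checksum), .payload_checksum(body)))
    stop("snapshot checksum mismatch: file corrupted", call. = FALSE)
  da <- lapply(pl$drug_amounts, .dec_num)
  names(da) <- pl$drug_names
  pairs <- lapply(pl$physio$pairs, .dec_num)
  pairs$name <- pl$physio$pair_names
  phys <- list(time = .dec_num(pl$physio$time),
               blood_volume = .dec_num(pl$physio$blood_volume),
               alb_p = .dec_num(pl$physio$alb_p),
               pairs = pairs,
               endo_dmg = .dec_num(pl$physio$endo_dmg),
               no_lag = .dec_num(pl$physio$no_lag),
               hemo = lapply(pl$physio$hemo, .dec_num),
               renal = lapply(pl$physio$renal, .dec_num),
               cum = lapply(pl$physio$cum, .dec_num))
  class(phys) <- "physio_state"
  inf <- data.frame(kind = as.character(pl$infusions$kind),
                    name = as.character(pl$infusions$name),
                    start = .dec_num(pl$infusions$start),
                    end = .dec_num(pl$infusions$end),
                    rate = .dec_num(pl$infusions$rate),
                    alb_rate = .dec_num(pl$infusions$alb_rate),
                    stringsAsFactors = FALSE)
  patient_snapshot(time = .dec_num(pl$time), air = .dec_num(pl$air),
                   R = .dec_num(pl$R), drug_amounts = da, physio = phys,
                   infusions = inf,
                   cum_fluid_ml = .dec_num(pl$cum_fluid_ml))
}
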