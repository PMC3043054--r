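# Ion-residue contact detection and primary/secondary encounter bookkeeping.
#
# A contact is a maximal interval during which at least one heavy atom of an
# entity (residue, single oxygen atom, or merged carboxylate pair) lies
# within the cutoff of the ion, with short gaps bridged. A contact is a
# secondary encounter when the ion reached it by transfer from another
# entity without ever leaving the first solvation shell in between;
# otherwise it is primary (arrival from the bulk).

#' Entity map for contact bookkeeping
#'
#' Maps protein atoms to the entities used for contact detection at a chosen
#' granularity:
#' \describe{
#'   \item{residue}{whole residues (`<RES><resid>`).}
#'   \item{atom}{individual heavy atoms.}
#'   \item{carbonyl_oxygen}{backbone carbonyl oxygens only, one entity per
#'     atom.}
#'   \item{sidechain_oxygen}{side-chain oxygens of polar/charged residues,
#'     with the two carboxylate oxygens of Asp/Glu merged into a single
#'     entity per residue.}
#' }
#'
#' @param atoms atom metadata ([atom_meta()]).
#' @param granularity one of the four levels above.
#' @return data.frame with `atom_id`, `entity` (character label; `NA` for
#'   atoms outside the granularity).
#' @export
contact_entities <- function(atoms,
                             granularity = c("residue", "atom",
                                             "carbonyl_oxygen",
                                             "sidechain_oxygen")) {
  granularity <- match.arg(granularity)
  lab_res <- paste0(atoms$residue_name, atoms$residue_id)
  ent <- switch(granularity,
    residue = lab_res,
    atom = paste0(lab_res, ":", atoms$atom_name),
    carbonyl_oxygen = ifelse(atoms$oxygen_class == "backbone_carbonyl",
                             paste0(lab_res, ":", atoms$atom_name),
                             NA_character_),
    sidechain_oxygen = ifelse(
      atoms$oxygen_class == "sidechain_carboxylate",
      paste0(lab_res, ":carboxylate"),
      ifelse(atoms$oxygen_class == "sidechain_other_polar",
             paste0(lab_res, ":", atoms$atom_name), NA_character_)))
  data.frame(atom_id = atoms$atom_id, entity = ent, stringsAsFactors = FALSE)
}

#' Contact intervals from a per-frame indicator matrix
#'
#' Run-length extraction with gap bridging, shared by [detect_contacts()]
#' and by generator-driven tests that supply the indicator directly.
#'
#' @param ind logical `n_frames x n_entities` matrix (dimnames give entity
#'   labels) — `TRUE` where the entity is in contact.
#' @param times frame times (ps), uniform.
#' @param grace_time gaps of at most this duration inside a contact are
#'   bridged (ps).
#' @return data.frame of class `"contact_intervals"`: `entity`, `t_start`,
#'   `t_end`, `duration`, `first_frame`, `last_frame`.
#' @export
contacts_from_indicator <- function(ind, times, grace_time = 2) {
  n <- nrow(ind)
  stopifnot(length(times) == n)
  dt <- if (n > 1L) times[2] - times[1] else 1
  g <- as.integer(floor(grace_time / dt))
  ents <- colnames(ind) %||% as.character(seq_len(ncol(ind)))
  out <- list()
  for (j in seq_len(ncol(ind))) {
    v <- bridge_gaps(ind[, j], g)
    if (!any(v)) next
    r <- rle(v)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      i0 <- starts[k]; i1 <- ends[k]
      out[[length(out) + 1L]] <- data.frame(
        entity = ents[j], t_start = times[i0],
        t_end = times[i0] + (i1 - i0 + 1L) * dt,
        duration = (i1 - i0 + 1L) * dt,
        first_frame = i0, last_frame = i1, stringsAsFactors = FALSE)
    }
  }
  ci <- if (length(out)) do.call(rbind, out) else
    data.frame(entity = character(0), t_start = numeric(0),
               t_end = numeric(0), duration = numeric(0),
               first_frame = integer(0), last_frame = integer(0))
  ci <- ci[order(ci$t_start, ci$entity), , drop = FALSE]
  rownames(ci) <- NULL
  structure(ci, class = c("contact_intervals", "data.frame"))
}

#' Detect ion-entity contacts in a trajectory
#'
#' @param traj an `ion_traj`.
#' @param ion_label which ion; default first.
#' @param cutoff contact distance in nm (default 0.35, the first-shell
#'   boundary; 0.30 is the tighter alternative).
#' @param granularity see [contact_entities()].
#' @param grace_time gap-bridging time (ps); the same short-excursion rule
#'   used for shell residence, extended to contacts (set 0 to disable).
#' @param heavy_only ignore hydrogens (default TRUE).
#' @param chunk frames per vectorised block.
#' @return a `contact_intervals` data.frame.
#' @export
detect_contacts <- function(traj, ion_label = NULL, cutoff = 0.35,
                            granularity = "residue", grace_time = 2,
                            heavy_only = TRUE, chunk = 1000L) {
  stopifnot(inherits(traj, "ion_traj"))
  ion_label <- ion_label %||% names(traj$ion_coords)[1]
  x <- traj$ion_coords[[ion_label]]
  if (is.null(x)) stop("unknown ion label: ", ion_label)
  emap <- contact_entities(traj$atoms, granularity)
  keep <- !is.na(emap$entity) &
    (if (heavy_only) traj$atoms$is_heavy else TRUE)
  if (!any(keep)) stop("no atoms at this granularity")
  rows <- which(keep)
  ents <- emap$entity[rows]
  ulev <- unique(ents)
  eid <- match(ents, ulev)
  n <- n_frames(traj)
  ind <- matrix(FALSE, n, length(ulev), dimnames = list(NULL, ulev))
  cut2 <- cutoff^2
  if (traj$static_protein) {
    P <- traj$protein_coords[rows, , drop = FALSE]
    m <- nrow(P)
    for (s in seq(1L, n, by = chunk)) {
      e <- min(s + chunk - 1L, n); nb <- e - s + 1L
      dx <- P[rep(seq_len(m), times = nb), , drop = FALSE] -
        x[rep(s:e, each = m), , drop = FALSE]
      bx <- traj$box[rep(s:e, each = m), , drop = FALSE]
      dx <- min_image(dx, bx)
      hit <- matrix(rowSums(dx * dx) <= cut2, nrow = m, ncol = nb)
      for (u in seq_along(ulev))
        ind[s:e, u] <- colSums(hit[eid == u, , drop = FALSE]) > 0L
    }
  } else {
    for (i in seq_len(n)) {
      P <- protein_frame(traj, i)[rows, , drop = FALSE]
      dx <- min_image(sweep(P, 2L, x[i, ]),
                      traj$box[rep(i, nrow(P)), , drop = FALSE])
      hit <- rowSums(dx * dx) <= cut2
      ind[i, ] <- tapply(hit, eid, any)[as.character(seq_along(ulev))]
    }
  }
  contacts_from_indicator(ind, traj$times, grace_time)
}

#' Classify contacts into primary and secondary encounters
#'
#' A contact is secondary when the ion remained continuously within the
#' first solvation shell (short exits bridged by the grace rule) from the end
#' of an earlier contact with a *different* entity to this contact's start;
#' its origin is the entity of the most recent such contact (a contact still
#' active at the start qualifies). Otherwise the contact is primary: the ion
#' arrived from the bulk.
#'
#' @param contacts a `contact_intervals` data.frame.
#' @param first_shell logical per-frame vector: ion within the first shell.
#' @param times frame times (ps).
#' @param grace_time bridging time for first-shell continuity (ps).
#' @return data.frame of class `"contact_events"`: the contact columns plus
#'   `classification` (`"primary"`/`"secondary"`) and `origin_entity` (`NA`
#'   for primary).
#' @export
classify_encounters <- function(contacts, first_shell, times,
                                grace_time = 2) {
  n <- length(first_shell)
  stopifnot(length(times) == n)
  dt <- if (n > 1L) times[2] - times[1] else 1
  fs <- bridge_gaps(first_shell, as.integer(floor(grace_time / dt)))
  # stretch_start[i]: first index of the maximal TRUE run covering i (NA if
  # fs[i] is FALSE)
  run_id <- cumsum(c(1L, diff(fs) != 0))
  run_first <- stats::ave(seq_len(n), run_id, FUN = min)
  cls <- character(nrow(contacts))
  org <- rep(NA_character_, nrow(contacts))
  ord <- order(contacts$first_frame, contacts$entity)
  for (ii in ord) {
    sf <- contacts$first_frame[ii]
    if (!fs[sf]) { cls[ii] <- "primary"; next }
    stretch <- run_first[sf]
    cand <- which(contacts$entity != contacts$entity[ii] &
                    contacts$first_frame < sf &
                    pmin(contacts$last_frame, sf) >= stretch)
    if (!length(cand)) { cls[ii] <- "primary"; next }
    eff_end <- pmin(contacts$last_frame[cand], sf)
    best <- cand[order(-eff_end, -contacts$first_frame[cand],
                       contacts$entity[cand])][1]
    cls[ii] <- "secondary"
    org[ii] <- contacts$entity[best]
  }
  out <- cbind(as.data.frame(contacts), classification = cls,
               origin_entity = org, stringsAsFactors = FALSE)
  structure(out, class = c("contact_events", "data.frame"))
}

#' Per-entity binding table
#'
#' Total binding time (union of the entity's contact intervals — intervals
#' for one entity are maximal and disjoint by construction), encounter
#' counts split by classification, and mean dwell time per contact.
#'
#' @param events a `contact_events` data.frame.
#' @return data.frame of class `"encounter_table"` with `entity`,
#'   `binding_time` (ps), `primary_count`, `secondary_count`, `mean_dwell`
#'   (ps), ordered by decreasing binding time.
#' @export
binding_table <- function(events) {
  if (!nrow(events))
    return(structure(data.frame(entity = character(0),
                                binding_time = numeric(0),
                                primary_count = integer(0),
                                secondary_count = integer(0),
                                mean_dwell = numeric(0)),
                     class = c("encounter_table", "data.frame")))
  sp <- split(events, events$entity)
  tab <- do.call(rbind, lapply(sp, function(g) data.frame(
    entity = g$entity[1],
    binding_time = sum(g$duration),
    primary_count = sum(g$classification == "primary"),
    secondary_count = sum(g$classification == "secondary"),
    mean_dwell = mean(g$duration), stringsAsFactors = FALSE)))
  tab <- tab[order(-tab$binding_time, tab$entity), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("encounter_table", "data.frame"))
}

#' Inter-entity transfer counts
#'
#' One count per secondary encounter, attributed to the unordered
#' `(origin, destination)` pair — transfers in either direction accumulate
#' on the same pair.
#'
#' @param events a `contact_events` data.frame.
#' @param pairs optional 2-column matrix/data.frame of entity pairs to
#'   report (others dropped); default all pairs observed.
#' @return data.frame of class `"transfer_counts"`: `entity_a`, `entity_b`
#'   (lexicographic order within the pair), `count`.
#' @export
transfer_counts <- function(events, pairs = NULL) {
  sec <- events[events$classification == "secondary", , drop = FALSE]
  mk <- function(a, b) {
    swap <- a > b
    data.frame(entity_a = ifelse(swap, b, a), entity_b = ifelse(swap, a, b),
               stringsAsFactors = FALSE)
  }
  if (nrow(sec)) {
    key <- mk(sec$origin_entity, sec$entity)
    agg <- stats::aggregate(list(count = rep(1L, nrow(key))), key, sum)
  } else {
    agg <- data.frame(entity_a = character(0), entity_b = character(0),
                      count = integer(0))
  }
  if (!is.null(pairs)) {
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    want <- mk(pairs[[1]], pairs[[2]])
    m <- merge(want, agg, all.x = TRUE)
    m$count[is.na(m$count)] <- 0L
    agg <- m
  }
  agg <- agg[order(agg$entity_a, agg$entity_b), , drop = FALSE]
  rownames(agg) <- NULL
  structure(agg, class = c("transfer_counts", "data.frame"))
}

#' Headline encounter statistics
#'
#' Pools all classified contacts into the summary quantities used to
#' characterise the encounter kinetics: the secondary/primary ratio (overall
#' and, when an entity-class map is given, per class), the mean time between
#' primary and between secondary encounters, the mean number of entities
#' contacted simultaneously while bound, and the fraction of time the ion is
#' free (no contact at all).
#'
#' @param events a `contact_events` data.frame.
#' @param times frame times (ps) of the underlying series.
#' @param total_time total simulated time (ps); default the series span.
#' @param class_map optional named character vector `entity -> class` for
#'   per-class ratios.
#' @return list of class `"encounter_summary"`: `n_primary`, `n_secondary`,
#'   `ratio`, `mean_primary_interval` (ps), `mean_secondary_interval` (ps),
#'   `mean_concurrency`, `free_fraction`, and `ratio_by_class` (or `NULL`).
#' @export
summary_stats <- function(events, times, total_time = NULL,
                          class_map = NULL) {
  n <- length(times)
  dt <- if (n > 1L) times[2] - times[1] else 1
  total_time <- total_time %||% (n * dt)
  if (total_time <= 0) stop("total_time must be positive")
  np <- sum(events$classification == "primary")
  ns <- sum(events$classification == "secondary")
  ratio <- if (np > 0L) ns / np else NA_real_
  pint <- if (np > 0L) total_time / np else NA_real_
  sint <- if (ns > 0L) total_time / ns else NA_real_
  cov <- integer(n)
  for (i in seq_len(nrow(events))) {
    idx <- events$first_frame[i]:events$last_frame[i]
    cov[idx] <- cov[idx] + 1L
  }
  rbc <- NULL
  if (!is.null(class_map)) {
    cl <- class_map[events$entity]
    rbc <- vapply(split(events$classification, cl), function(v) {
      p <- sum(v == "primary")
      if (p > 0L) sum(v == "secondary") / p else NA_real_
    }, numeric(1))
  }
  structure(list(
    n_primary = np, n_secondary = ns, ratio = ratio,
    mean_primary_interval = pint, mean_secondary_interval = sint,
    mean_concurrency = if (any(cov > 0L)) mean(cov[cov > 0L]) else NA_real_,
    free_fraction = mean(cov == 0L),
    ratio_by_class = rbc), class = "encounter_summary")
}

#' @export
print.encounter_summary <- function(x, ...) {
  cat("Encounter summary\n")
  cat(sprintf("  primary: %d, secondary: %d, secondary/primary = %s\n",
              x$n_primary, x$n_secondary, format(x$ratio, digits = 3)))
  cat(sprintf("  mean interval between primary encounters:   %s ps\n",
              format(x$mean_primary_interval, digits = 4)))
  cat(sprintf("  mean interval between secondary encounters: %s ps\n",
              format(x$mean_secondary_interval, digits = 4)))
  cat(sprintf("  mean simultaneous contacts while bound: %s\n",
              format(x$mean_concurrency, digits = 3)))
  cat(sprintf("  free fraction: %s\n", format(x$free_fraction, digits = 3)))
  if (!is.null(x$ratio_by_class)) {
    cat("  secondary/primary by class:\n")
    for (nm in names(x$ratio_by_class))
      cat(sprintf("    %s: %s\n", nm,
                  format(x$ratio_by_class[[nm]], digits = 3)))
  }
  invisible(x)
}

#' Pooled statistics from a printed encounter table
#'
#' Works on a binding-time/encounter-count table of the shape shipped in
#' `inst/extdata/table2_encounters.csv` (per-residue binding times and
#' primary/secondary counts for two protein variants). Pools the counts of
#' all variants and reports the secondary/primary ratio and the mean time
#' between encounters given the total simulated time.
#'
#' @param tab data.frame with columns `residue` and, per variant prefix,
#'   `<v>_binding_time`, `<v>_primary`, `<v>_secondary`.
#' @param total_time_ns total simulated time across all pooled variants, ns.
#' @return list of class `"encounter_summary_table"`: pooled counts, `ratio`,
#'   `mean_primary_interval_ns`, `mean_secondary_interval_ns`.
#' @export
summarize_encounter_table <- function(tab, total_time_ns) {
  pc <- grep("_primary$", names(tab), value = TRUE)
  sc <- grep("_secondary$", names(tab), value = TRUE)
  if (!length(pc) || !length(sc)) stop("no *_primary / *_secondary columns")
  np <- sum(vapply(tab[pc], function(v) sum(v, na.rm = TRUE), numeric(1)))
  ns <- sum(vapply(tab[sc], function(v) sum(v, na.rm = TRUE), numeric(1)))
  structure(list(n_primary = np, n_secondary = ns,
                 ratio = ns / np,
                 mean_primary_interval_ns = total_time_ns / np,
                 mean_secondary_interval_ns = total_time_ns / ns),
            class = "encounter_summary_table")
}

#' @export
print.encounter_summary_table <- function(x, ...) {
  cat(sprintf(paste0("Pooled table: %d primary, %d secondary; ",
                     "secondary/primary = %.3f\n"),
              x$n_primary, x$n_secondary, x$ratio))
  cat(sprintf("  mean primary interval:   %.3f ns\n",
              x$mean_primary_interval_ns))
  cat(sprintf("  mean secondary interval: %.3f ns\n",
              x$mean_secondary_interval_ns))
  invisible(x)
}
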