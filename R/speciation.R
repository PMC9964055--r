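#' Microspecies fractions from a pKa ladder
#'
#' Computes the population fraction of each protonation macrostate of a
#' compound at a given pH using the sequential Henderson--Hasselbalch
#' ladder: with the pKa values sorted ascending, the macrostate that has
#' lost `j` protons carries relative weight `10^(j*pH - sum(pKa[1:j]))`.
#' Fractions are the normalized weights and sum to 1 exactly. Weights are
#' computed on the log10 scale with a max-shift so extreme pH values cannot
#' overflow.
#'
#' Site types only affect the charge labels (a basic site contributes +1 to
#' the fully protonated state), not the fractions. Users who prefer
#' externally computed microspecies fractions (e.g. from full microstate
#' enumeration by vendor software) can pass them directly to
#' [weighted_descriptors()].
#'
#' @param pka_values Numeric vector of pKa values, sorted ascending. An
#'   empty vector yields a single species with fraction 1.
#' @param site_types Character vector (`"acidic"` or `"basic"`), one per
#'   pKa; used only to label species charges.
#' @param ph The pH at which to speciate.
#' @return A tibble with one row per macrostate: `species` (label),
#'   `n_deprotonated`, `charge` and `fraction`.
#' @export
#' @examples
#' speciate(4.0, "acidic", ph = 4.0)      # 50/50 at pH = pKa
#' speciate(c(3, 8), c("acidic", "acidic"), ph = 5)
speciate <- function(pka_values, site_types = rep("acidic", length(pka_values)),
                     ph) {
  if (length(pka_values) && any(!is.finite(pka_values))) {
    qsrr_abort("`pka_values` must all be finite.")
  }
  if (!is.numeric(ph) || length(ph) != 1L || !is.finite(ph)) {
    qsrr_abort("`ph` must be a single finite number.")
  }
  if (length(site_types) != length(pka_values)) {
    qsrr_abort("`site_types` must have one entry per pKa value.")
  }
  if (length(site_types) && !all(site_types %in% c("acidic", "basic"))) {
    qsrr_abort("`site_types` entries must be \"acidic\" or \"basic\".")
  }
  if (length(pka_values) > 1L && is.unsorted(pka_values)) {
    qsrr_abort("`pka_values` must be sorted ascending for the sequential ladder.")
  }

  m <- length(pka_values)
  j <- 0:m
  # log10 relative weight of losing the first j protons
  logw <- j * ph - c(0, cumsum(pka_values))
  logw <- logw - max(logw)
  w <- 10^logw
  fractions <- w / sum(w)

  charge_full <- sum(site_types == "basic")
  charge <- charge_full - j
  label <- ifelse(charge == 0, "neutral",
                  sprintf("%s%d", ifelse(charge > 0, "cation", "anion"),
                          abs(charge)))
  label[charge == 1] <- "cation"
  label[charge == -1] <- "anion"

  tibble::tibble(
    species = make.unique(label),
    n_deprotonated = j,
    charge = as.integer(charge),
    fraction = fractions
  )
}

#' Build a microspecies profile for one compound
#'
#' Bundles the per-species descriptor values of a compound with its pKa
#' ladder and pH-dependent logD values. All species must share the same
#' descriptor names.
#'
#' @param compound_id Compound identifier.
#' @param species A tibble/data.frame with a `species` label column and one
#'   numeric column per descriptor (one row per protonation state).
#' @param pka_values,site_types Passed to [speciate()]; may be empty for a
#'   non-ionizable compound.
#' @param logd_by_ph Named numeric vector mapping pH (as character, e.g.
#'   `"2.7"`) to the compound's logD at that pH.
#' @return A `microspecies_profile` object.
#' @export
microspecies_profile <- function(compound_id, species, pka_values = numeric(),
                                 site_types = rep("acidic", length(pka_values)),
                                 logd_by_ph = numeric()) {
  species <- tibble::as_tibble(species)
  if (!"species" %in% names(species)) {
    qsrr_abort("`species` must contain a `species` label column.")
  }
  desc_cols <- setdiff(names(species), "species")
  if (!length(desc_cols)) qsrr_abort("`species` must contain descriptor columns.")
  bad <- desc_cols[!vapply(species[desc_cols], is.numeric, logical(1))]
  if (length(bad)) {
    qsrr_abort(sprintf("Non-numeric descriptor columns: %s.",
                       paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(species$species)) {
    qsrr_abort("Species labels must be unique within a compound.")
  }
  if (length(pka_values) && any(!is.finite(pka_values))) {
    qsrr_abort("`pka_values` must all be finite.")
  }
  expected <- length(pka_values) + 1L
  if (nrow(species) != expected) {
    qsrr_abort(sprintf(
      "Compound %s: %d pKa value(s) imply %d sequential macrostates but %d species rows were given.",
      compound_id, length(pka_values), expected, nrow(species)
    ))
  }
  structure(
    list(compound_id = as.character(compound_id), species = species,
         pka_values = as.numeric(pka_values),
         site_types = as.character(site_types),
         logd_by_ph = logd_by_ph),
    class = "microspecies_profile"
  )
}

#' @export
print.microspecies_profile <- function(x, ...) {
  cat(sprintf("<microspecies_profile> %s: %d species, %d descriptors, %d pKa\n",
              x$compound_id, nrow(x$species), ncol(x$species) - 1L,
              length(x$pka_values)))
  invisible(x)
}

#' Microspecies-weighted descriptor vector
#'
#' Averages a compound's per-species descriptor values with the microspecies
#' population fractions at the pH of interest as weights, and appends the
#' compound's logD at that pH (when available) as an extra descriptor. This
#' is how pH-dependent descriptor matrices are assembled: each descriptor of
#' the compound at pH `x` is the fraction-weighted mean over its protonation
#' states.
#'
#' @param profile A [microspecies_profile()].
#' @param speciation Either a tibble from [speciate()] (columns `species`,
#'   `fraction`) or a named numeric vector of fractions. Labels must match
#'   the profile's species rows; fractions must sum to 1 within 1e-8.
#' @param ph Optional pH used to look up logD in the profile; when `NULL`
#'   no logD column is appended.
#' @return A named numeric vector (descriptors, plus `logD` when appended).
#' @export
weighted_descriptors <- function(profile, speciation, ph = NULL) {
  stopifnot(inherits(profile, "microspecies_profile"))
  if (is.data.frame(speciation)) {
    fr <- stats::setNames(speciation$fraction, speciation$species)
  } else {
    fr <- speciation
  }
  if (is.null(names(fr)) || !length(fr)) {
    qsrr_abort("Speciation fractions must be named by species label.")
  }
  missing_sp <- setdiff(names(fr), profile$species$species)
  if (length(missing_sp)) {
    qsrr_abort(sprintf("Species absent from profile %s: %s.",
                       profile$compound_id, paste(missing_sp, collapse = ", ")))
  }
  if (abs(sum(fr) - 1) > 1e-8) {
    qsrr_abort("Speciation fractions must sum to 1.")
  }
  desc_cols <- setdiff(names(profile$species), "species")
  M <- as.matrix(profile$species[desc_cols])
  rownames(M) <- profile$species$species
  out <- drop(fr %*% M[names(fr), , drop = FALSE])
  if (!is.null(ph)) {
    key <- as.character(ph)
    if (key %in% names(profile$logd_by_ph)) {
      out <- c(out, logD = unname(profile$logd_by_ph[[key]]))
    } else {
      qsrr_abort(sprintf("Profile %s has no logD at pH %s.",
                         profile$compound_id, key))
    }
  }
  out
}

#' Assemble a pH-specific descriptor matrix from microspecies profiles
#'
#' Speciation is computed from each profile's pKa ladder at `ph`, descriptor
#' values are fraction-weighted per compound, and logD at `ph` is appended,
#' yielding the compounds x descriptors table used for QSRR modeling at that
#' pH.
#'
#' @param profiles List of [microspecies_profile()] objects sharing one
#'   descriptor-name set.
#' @param ph The pH condition.
#' @return A tibble: `compound_id` plus one column per descriptor (shared
#'   names, then `logD`), rows in input order.
#' @export
build_descriptor_matrix <- function(profiles, ph) {
  if (!length(profiles)) qsrr_abort("`profiles` must be nonempty.")
  ids <- vapply(profiles, function(p) p$compound_id, character(1))
  if (anyDuplicated(ids)) {
    qsrr_abort(sprintf("Duplicate compound ids: %s.",
                       paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  ref_names <- setdiff(names(profiles[[1L]]$species), "species")
  for (p in profiles) {
    nm <- setdiff(names(p$species), "species")
    if (!setequal(nm, ref_names)) {
      qsrr_abort(sprintf(
        "Profile %s descriptor names differ from the first profile (missing: %s; extra: %s).",
        p$compound_id,
        paste(setdiff(ref_names, nm), collapse = ", "),
        paste(setdiff(nm, ref_names), collapse = ", ")
      ))
    }
  }
  rows <- purrr::map(profiles, function(p) {
    sp <- speciate(p$pka_values, p$site_types, ph)
    # Profiles list species in ladder order (fully protonated first), so
    # fractions are matched by position regardless of the labels used.
    fr <- stats::setNames(sp$fraction, p$species$species)
    v <- weighted_descriptors(p, fr, ph = ph)
    tibble::as_tibble(as.list(v[c(ref_names, "logD")]))
  })
  dplyr::bind_cols(tibble::tibble(compound_id = ids), dplyr::bind_rows(rows))
}

#' Read microspecies profiles from JSON
#'
#' Expects an array of objects with fields `compound_id`, `species` (object
#' label -> descriptor object), `pka_values`, `site_types`, `logd_by_ph`.
#'
#' @param path JSON file path.
#' @return List of [microspecies_profile()] objects.
#' @export
read_microspecies_profiles <- function(path) {
  raw <- jsonlite::read_json(path)
  purrr::map(raw, function(r) {
    sp <- purrr::imap(r$species, function(desc, label) {
      tibble::as_tibble(c(list(species = label), desc))
    }) |> dplyr::bind_rows()
    microspecies_profile(
      compound_id = r$compound_id,
      species = sp,
      pka_values = as.numeric(unlist(r$pka_values)),
      site_types = as.character(unlist(r$site_types %||% rep("acidic", length(r$pka_values)))),
      logd_by_ph = unlist(r$logd_by_ph)
    )
  })
}
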