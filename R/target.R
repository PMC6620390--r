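#' Assign postsynaptic targets to synaptic junctions
#'
#' The postsynaptic object of each junction is the non-synapse object with
#' the largest face-contact area (ties broken by lowest object ID). Spine
#' heads and necks must be traceable to a parent dendrite through the
#' label adjacency graph (head -> neck -> shaft); a spine that cannot be
#' traced — its neck cut by the volume border — yields `unknown`, mirroring
#' the rule that truncated postsynaptic elements cannot be conclusively
#' identified. Shaft targets are split by the target dendrite's spininess,
#' assessed purely from spines attached inside the volume.
#'
#' @param volume A [labeled_volume()].
#' @param synapse_ids IDs to classify; default all objects of class
#'   `synapse`.
#' @param adjacency Optional precomputed [volume_adjacency()] table.
#' @return Tibble: `synapse_id`, `target_class` (`spine_head`, `spine_neck`,
#'   `aspiny_shaft`, `spiny_shaft`, `unknown`), `postsynaptic_object_id`,
#'   `traced_to_parent`, `contact_area_nm2`.
#' @export
assign_targets <- function(volume, synapse_ids = NULL, adjacency = NULL) {
  objects <- volume$objects
  synapse_ids <- synapse_ids %||%
    objects$object_id[objects$class == "synapse"]
  adjacency <- adjacency %||% volume_adjacency(volume)
  cls <- setNames(objects$class, objects$object_id)
  trunc <- setNames(objects$truncated, objects$object_id)

  # Long adjacency: one row per (object, neighbour).
  adj_long <- dplyr::bind_rows(
    dplyr::transmute(adjacency, id = .data$id_a, nb = .data$id_b,
      area = .data$contact_area_nm2),
    dplyr::transmute(adjacency, id = .data$id_b, nb = .data$id_a,
      area = .data$contact_area_nm2)
  )
  nb_of <- split(adj_long[c("nb", "area")], adj_long$id)

  neighbours <- function(id, class_filter = NULL) {
    nb <- nb_of[[as.character(id)]]
    if (is.null(nb)) return(integer(0))
    ids <- nb$nb
    if (!is.null(class_filter)) ids <- ids[cls[as.character(ids)] %in% class_filter]
    ids
  }
  # Dendrites with at least one attached spine neck inside the volume.
  dendrite_ids <- objects$object_id[objects$class == "dendrite_shaft"]
  spiny <- vapply(dendrite_ids, function(d) {
    length(neighbours(d, "spine_neck")) > 0
  }, logical(1))
  names(spiny) <- dendrite_ids

  n <- length(synapse_ids)
  target <- character(n)
  post_id <- integer(n)
  traced <- rep(NA, n)
  carea <- numeric(n)
  for (i in seq_len(n)) {
    sid <- synapse_ids[i]
    nb <- nb_of[[as.character(sid)]]
    if (!is.null(nb)) {
      keep <- cls[as.character(nb$nb)] != "synapse"
      nb <- nb[keep, , drop = FALSE]
    }
    if (is.null(nb) || nrow(nb) == 0) {
      # a truncated junction can legitimately lose its contact at the border;
      # anywhere else a contactless synapse is a malformed scene
      if (isTRUE(trunc[[as.character(sid)]])) {
        target[i] <- "unknown"
        traced[i] <- FALSE
        post_id[i] <- NA_integer_
        carea[i] <- 0
        next
      }
      abort(sprintf("synapse %d has no postsynaptic contact: malformed scene", sid))
    }
    best <- nb[order(-nb$area, nb$nb), , drop = FALSE][1, ]
    post <- best$nb
    post_cls <- cls[[as.character(post)]]
    if (post_cls == "spine_head") {
      neck <- neighbours(post, "spine_neck")
      shaft <- if (length(neck)) neighbours(neck[1], "dendrite_shaft") else integer(0)
      if (length(neck) && length(shaft)) {
        target[i] <- "spine_head"; traced[i] <- TRUE
      } else {
        target[i] <- "unknown"; traced[i] <- FALSE
      }
    } else if (post_cls == "spine_neck") {
      if (length(neighbours(post, "dendrite_shaft"))) {
        target[i] <- "spine_neck"; traced[i] <- TRUE
      } else {
        target[i] <- "unknown"; traced[i] <- FALSE
      }
    } else if (post_cls == "dendrite_shaft") {
      target[i] <- if (isTRUE(spiny[[as.character(post)]])) {
        "spiny_shaft"
      } else {
        "aspiny_shaft"
      }
    } else {
      target[i] <- "unknown"; traced[i] <- FALSE
    }
    post_id[i] <- post
    carea[i] <- best$area
  }
  tibble::tibble(
    synapse_id = synapse_ids,
    target_class = target,
    postsynaptic_object_id = post_id,
    traced_to_parent = traced,
    contact_area_nm2 = carea
  )
}

#' @rdname assign_targets
#' @param synapse_id A single junction ID.
#' @export
assign_target <- function(volume, synapse_id, adjacency = NULL) {
  assign_targets(volume, synapse_id, adjacency)
}

#' Single and multiple synapses per spine head
#'
#' Tabulates, for every spine head that receives at least one synapse, the
#' composition of its synapses by type, and summarises the composition
#' frequencies over occupied heads in the usual bins: single AS, single SS,
#' two AS, one AS + one SS, two AS + one SS, and other combinations.
#'
#' @param targets Output of [assign_targets()].
#' @param types Tibble with `synapse_id` and `type` (`"AS"`/`"SS"`), e.g.
#'   from [classify_types()] or the scene ground truth.
#' @return List with `occupancy` (per-head tibble: `spine_head_id`,
#'   `n_AS`, `n_SS`, `composition`) and `frequency` (tibble:
#'   `composition`, `n_heads`, `percent`).
#' @export
spine_occupancy <- function(targets, types) {
  heads <- dplyr::filter(targets, .data$target_class == "spine_head")
  if (nrow(heads) == 0) {
    return(list(
      occupancy = tibble::tibble(
        spine_head_id = integer(0), n_AS = integer(0), n_SS = integer(0),
        composition = character(0)
      ),
      frequency = tibble::tibble(
        composition = character(0), n_heads = integer(0), percent = numeric(0)
      )
    ))
  }
  occ <- heads |>
    dplyr::left_join(types[c("synapse_id", "type")], by = "synapse_id") |>
    dplyr::group_by(spine_head_id = .data$postsynaptic_object_id) |>
    dplyr::summarise(
      n_AS = sum(.data$type == "AS"),
      n_SS = sum(.data$type == "SS"),
      .groups = "drop"
    ) |>
    dplyr::mutate(composition = dplyr::case_when(
      n_AS == 1 & n_SS == 0 ~ "single_AS",
      n_AS == 0 & n_SS == 1 ~ "single_SS",
      n_AS == 2 & n_SS == 0 ~ "two_AS",
      n_AS == 1 & n_SS == 1 ~ "AS_SS",
      n_AS == 2 & n_SS == 1 ~ "two_AS_SS",
      .default = "other"
    ))
  freq <- occ |>
    dplyr::count(.data$composition, name = "n_heads") |>
    dplyr::mutate(percent = 100 * .data$n_heads / sum(.data$n_heads))
  list(occupancy = occ, frequency = freq)
}
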