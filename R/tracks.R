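# Track cleaning: duration and movement filters, clash resolution, staged
# fragment joining, and per-sample temperature assignment.
#
# A track table is a long data.frame with columns id, frame, t, x, y,
# head_x, head_y, bend_deg (mm and seconds); temp_C is added by
# assign_temperature().

# Internal: per-track endpoint summary.
track_endpoints <- function(tracks) {
  sp <- split(seq_len(nrow(tracks)), tracks$id)
  ids <- as.integer(names(sp))
  first <- vapply(sp, function(i) i[which.min(tracks$frame[i])], integer(1))
  last <- vapply(sp, function(i) i[which.max(tracks$frame[i])], integer(1))
  data.frame(id = ids,
             f0 = tracks$frame[first], f1 = tracks$frame[last],
             t0 = tracks$t[first], t1 = tracks$t[last],
             x0 = tracks$x[first], y0 = tracks$y[first],
             x1 = tracks$x[last], y1 = tracks$y[last])
}

#' Drop short tracks
#'
#' Removes raw tracks whose duration is strictly less than
#' `min_duration_s` (a track lasting exactly the threshold is kept).
#' Applied to raw tracks before any joining.
#'
#' @param tracks track data.frame.
#' @param min_duration_s minimum duration, s.
#' @return Filtered track data.frame.
#' @export
filter_short <- function(tracks, min_duration_s = 10) {
  if (nrow(tracks) == 0) return(tracks)
  dur <- tapply(tracks$t, tracks$id, function(t) max(t) - min(t))
  keep <- names(dur)[dur >= min_duration_s]
  tracks[tracks$id %in% as.integer(keep), , drop = FALSE]
}

#' Drop non-moving tracks
#'
#' A track is removed iff its cumulative path length is at most
#' `min_cum_mm` AND its maximum displacement from the first sample is at
#' most `min_net_mm` (both criteria must indicate non-movement).
#'
#' @param tracks track data.frame (coordinates in mm).
#' @param min_cum_mm cumulative path threshold, mm.
#' @param min_net_mm net displacement threshold, mm.
#' @return Filtered track data.frame.
#' @export
filter_nonmoving <- function(tracks, min_cum_mm = 0.5, min_net_mm = 0.3) {
  if (nrow(tracks) == 0) return(tracks)
  sp <- split(seq_len(nrow(tracks)), tracks$id)
  nonmover <- vapply(sp, function(i) {
    i <- i[order(tracks$frame[i])]
    x <- tracks$x[i]; y <- tracks$y[i]
    cum <- sum(sqrt(diff(x)^2 + diff(y)^2))
    net <- max(sqrt((x - x[1])^2 + (y - y[1])^2))
    cum <= min_cum_mm && net <= min_net_mm
  }, logical(1))
  drop_ids <- as.integer(names(sp))[nonmover]
  tracks[!(tracks$id %in% drop_ids), , drop = FALSE]
}

# Internal: perform one pass of mutual-nearest joins given admissible
# candidate pairs. `pairs` has columns pred, succ, dt, dd. Ranking is
# lexicographic (dt first, then dd), ties broken by smaller partner id.
# Returns the join list (pred, succ) selected this pass.
mutual_pairs <- function(pairs) {
  if (nrow(pairs) == 0) return(pairs[0, c("pred", "succ"), drop = FALSE])
  best_for <- function(keys, other) {
    out <- integer(0); names_out <- character(0)
    for (k in unique(keys)) {
      sub <- pairs[keys == k, , drop = FALSE]
      o <- order(sub$dt, sub$dd, sub[[other]])
      out <- c(out, sub[[other]][o[1]])
      names_out <- c(names_out, as.character(k))
    }
    names(out) <- names_out
    out
  }
  best_succ <- best_for(pairs$pred, "succ")
  best_pred <- best_for(pairs$succ, "pred")
  sel <- pairs[best_succ[as.character(pairs$pred)] == pairs$succ &
                 best_pred[as.character(pairs$succ)] == pairs$pred,
               c("pred", "succ"), drop = FALSE]
  unique(sel)
}

# Internal: concatenate each succ track onto its pred under the earliest
# id of the join chain (a pass may select X->Y and Y->Z simultaneously;
# chains are acyclic because a successor always starts after its
# predecessor ends).
apply_joins <- function(tracks, joins) {
  resolve <- function(p) {
    while (p %in% joins$succ) p <- joins$pred[match(p, joins$succ)]
    p
  }
  for (i in seq_len(nrow(joins))) {
    tracks$id[tracks$id == joins$succ[i]] <- resolve(joins$pred[i])
  }
  tracks[order(tracks$id, tracks$frame), , drop = FALSE]
}

#' Resolve larva-clash track splits
#'
#' When two larvae collide the tracker loses both identities: two tracks
#' end abruptly on the same frame and new tracks start just after. At every
#' frame where at least two tracks end, each ended track is paired with the
#' candidate track starting soonest afterwards whose start point is
#' reciprocally closest (ranking lexicographic: time gap first, then
#' spatial gap); mutual pairs are concatenated under the earlier track's
#' id. Repeated until no further joins.
#'
#' @param tracks track data.frame, time-sorted within tracks.
#' @return Track data.frame with clash pairs joined; an attribute
#'   `"joins"` records the merges.
#' @export
join_clashes <- function(tracks) {
  if (nrow(tracks) == 0) return(tracks)
  audit <- data.frame(pred = integer(0), succ = integer(0))
  repeat {
    ep <- track_endpoints(tracks)
    end_counts <- table(ep$f1)
    clash_frames <- as.integer(names(end_counts)[end_counts >= 2])
    if (length(clash_frames) == 0) break
    preds <- ep[ep$f1 %in% clash_frames, , drop = FALSE]
    pairs <- do.call(rbind, lapply(seq_len(nrow(preds)), function(i) {
      px <- preds[i, ]
      cand <- ep[ep$f0 > px$f1, , drop = FALSE]
      if (nrow(cand) == 0) return(NULL)
      data.frame(pred = px$id, succ = cand$id,
                 dt = cand$t0 - px$t1,
                 dd = sqrt((cand$x0 - px$x1)^2 + (cand$y0 - px$y1)^2))
    }))
    if (is.null(pairs) || nrow(pairs) == 0) break
    joins <- mutual_pairs(pairs)
    if (nrow(joins) == 0) break
    audit <- rbind(audit, joins)
    tracks <- apply_joins(tracks, joins)
  }
  attr(tracks, "joins") <- audit
  tracks
}

#' Rejoin fragmented tracks in staged rounds
#'
#' Tracking dropouts split one larva's path into disjoint fragments. Pairs
#' (end of X, start of Y with Y starting after X ends) are joined when the
#' spatial gap, temporal gap and implied gap speed fall within the round's
#' limits; within a round only reciprocally closest pairs (time priority,
#' then distance) are joined, iterating until no further joins. Default
#' rounds: (150 px, 22.5 s, < 15 px/s), (500 px, 75 s, < 30 px/s), then
#' unrestricted.
#'
#' @param tracks track data.frame (after [join_clashes()]).
#' @param px_per_mm camera scale used to express gaps in px.
#' @param rounds data.frame with columns `dist_px`, `time_s`, `speed_px_s`.
#' @return Track data.frame with fragments joined; attribute `"joins"`
#'   records merges and the round in which each occurred.
#' @export
join_fragments <- function(tracks, px_per_mm = 4,
                           rounds = data.frame(
                             dist_px = c(150, 500, Inf),
                             time_s = c(22.5, 75, Inf),
                             speed_px_s = c(15, 30, Inf))) {
  if (nrow(tracks) == 0) return(tracks)
  audit <- data.frame(pred = integer(0), succ = integer(0),
                      round = integer(0))
  for (r in seq_len(nrow(rounds))) {
    repeat {
      ep <- track_endpoints(tracks)
      pairs <- do.call(rbind, lapply(seq_len(nrow(ep)), function(i) {
        px <- ep[i, ]
        cand <- ep[ep$f0 > px$f1, , drop = FALSE]
        if (nrow(cand) == 0) return(NULL)
        dt <- cand$t0 - px$t1
        dd_px <- sqrt((cand$x0 - px$x1)^2 + (cand$y0 - px$y1)^2) * px_per_mm
        ok <- dd_px <= rounds$dist_px[r] & dt <= rounds$time_s[r] &
          dd_px / dt < rounds$speed_px_s[r]
        if (!any(ok)) return(NULL)
        data.frame(pred = px$id, succ = cand$id[ok],
                   dt = dt[ok], dd = dd_px[ok])
      }))
      if (is.null(pairs) || nrow(pairs) == 0) break
      joins <- mutual_pairs(pairs)
      if (nrow(joins) == 0) break
      audit <- rbind(audit, cbind(joins, round = r))
      tracks <- apply_joins(tracks, joins)
    }
  }
  attr(tracks, "joins") <- audit
  tracks
}

#' Assign a temperature to every larva-frame
#'
#' Each sample takes the value of the thermal frame nearest in time (ties
#' broken toward the earlier frame) at the pixel nearest the larva's head
#' (thermosensors sit at the head tip); centroid lookup is available via
#' `body_part`. Positions outside the pixel grid are clamped to the
#' nearest edge pixel and flagged in `temp_clamped`.
#'
#' @param tracks track data.frame.
#' @param series a QC-passed [thermal_frames()] object.
#' @param body_part `"head"` (default) or `"centroid"`.
#' @return The track table with `temp_C` and `temp_clamped` columns.
#' @export
assign_temperature <- function(tracks, series,
                               body_part = c("head", "centroid")) {
  body_part <- match.arg(body_part)
  stopifnot(inherits(series, "thermal_frames"))
  if (nrow(tracks) == 0) {
    tracks$temp_C <- numeric(0); tracks$temp_clamped <- logical(0)
    return(tracks)
  }
  xx <- if (body_part == "head") tracks$head_x else tracks$x
  yy <- if (body_part == "head") tracks$head_y else tracks$y
  nr <- series$shape[1]; nc <- series$shape[2]
  cx <- floor(xx / series$arena_mm[1] * (nc - 1) + 0.5)
  cy <- floor(yy / series$arena_mm[2] * (nr - 1) + 0.5)
  clamped <- cx < 0 | cx > nc - 1 | cy < 0 | cy > nr - 1
  cx <- pmin(pmax(cx, 0), nc - 1)
  cy <- pmin(pmax(cy, 0), nr - 1)
  fidx <- nearest_frame_index(tracks$t, series$timestamps)
  temp <- numeric(nrow(tracks))
  for (f in unique(fidx)) {
    rows <- fidx == f
    temp[rows] <- series$frames[[f]][cbind(cy[rows] + 1, cx[rows] + 1)]
  }
  tracks$temp_C <- temp
  tracks$temp_clamped <- clamped
  tracks
}
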