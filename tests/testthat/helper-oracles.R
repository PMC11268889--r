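# independent oracle: scan the full merged event stream per strike
oracle_outcomes <- function(strikes, landings, feeding, nest_visits,
                            nest_position = c(0, 0), nest_radius = 30) {
  n_l <- nrow(landings); n_f <- nrow(feeding); n_n <- nrow(nest_visits)
  ev <- data.frame(
    t = c(landings$sec, feeding$t_start, nest_visits$t_enter),
    kind = c(ifelse(landings$subtype == "strike", "strike", "perch"),
             rep("feed", n_f), rep("nest", n_n)),
    x = c(if ("x" %in% names(landings)) landings$x else rep(NA, n_l),
          rep(NA, n_f + n_n)),
    y = c(if ("y" %in% names(landings)) landings$y else rep(NA, n_l),
          rep(NA, n_f + n_n))
  )
  ev <- ev[order(ev$t), ]
  sapply(strikes$sec, function(s) {
    for (i in which(ev$t > s)) {
      k <- ev$kind[i]
      if (k %in% c("feed", "nest")) return(TRUE)
      if (k == "perch" && !is.na(ev$x[i]) &&
          sqrt((ev$x[i] - nest_position[1])^2 +
                 (ev$y[i] - nest_position[2])^2) <= nest_radius) next
      return(FALSE)
    }
    FALSE
  })
}
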