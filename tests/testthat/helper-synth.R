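# shared fixtures: small designs and generator configs built in code

tiny_design <- function(n_blocks = 1, n_repetitions = 5, ...) {
  session_design(n_blocks = n_blocks, n_repetitions = n_repetitions, ...)
}

# epochs with a single planted component and everything else switched off
planted_epochs <- function(design = tiny_design(),
                           component = component_spec(
                             "P300", 450, width_ms = 60,
                             amplitude_mean = 5, amplitude_sd = 0,
                             latency_jitter_sd = 0,
                             topography = topography_gaussian("Pz"),
                             applies_to = "target"),
                           noise_sd = 0, seed = 1, sampling_rate = 200) {
  cfg <- generator_config(sampling_rate = sampling_rate,
                          components = list(component),
                          noise_sd = noise_sd)
  generate_epochs(design, cfg, seed = seed, sampling_rate = sampling_rate)
}

# hand-built epoch container around an explicit data array
make_epochs <- function(data, sampling_rate = 200, t_min = -200,
                        names_per_rep = NULL) {
  n_ep <- dim(data)[1]
  n_ch <- dim(data)[2]
  n_t <- dim(data)[3]
  time_ms <- t_min + (seq_len(n_t) - 1) / sampling_rate * 1000
  if (is.null(names_per_rep)) {
    name_id <- rep_len(c("SON", "ON1"), n_ep)
  } else {
    name_id <- rep_len(names_per_rep, n_ep)
  }
  aerp_epochs(data, time_ms, sampling_rate,
              paste0("ch", seq_len(n_ch)),
              data.frame(name_id = name_id,
                         is_target = name_id == "SON",
                         block = 0L,
                         repetition = seq_len(n_ep) - 1L))
}

# feature object with a controllable class separation on the first feature
make_features <- function(n_per_name = 20, delta = 0, noise = 1,
                          n_features = 4, seed = 1,
                          names = c("SON", "ON1", "ON2", "ON3", "ON4")) {
  set.seed(seed)
  name_id <- rep(names, each = n_per_name)
  y <- ifelse(name_id == "SON", 1L, -1L)
  x <- matrix(rnorm(length(y) * n_features, sd = noise),
              ncol = n_features)
  x[, 1] <- x[, 1] + ifelse(y == 1, delta, 0)
  colnames(x) <- paste0("T1.f", seq_len(n_features))
  n_rep <- n_per_name
  structure(list(x = x, y = y, name_id = name_id,
                 block = rep(0L, length(y)),
                 repetition = rep(seq_len(n_per_name) - 1L,
                                  times = length(names)),
                 window = rep("T1", n_features),
                 channel = colnames(x),
                 target = "SON"),
            class = "aerp_features")
}

# r2 map object with explicit values, for selection-score arithmetic
make_map <- function(values, time_ms) {
  structure(list(values = values, time_ms = time_ms,
                 channel_labels = rownames(values) %||%
                   paste0("ch", seq_len(nrow(values))),
                 n_target = 10, n_nontarget = 10),
            class = "aerp_r2map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
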