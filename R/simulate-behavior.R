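# Synthetic recognition-memory sessions with a controllable novelty
# preference.

#' Parameters for the behavioral session generator
#'
#' @param n_bouts Number of investigation bouts per session.
#' @param mean_bout Mean bout duration in seconds (exponential).
#' @param preference Expected retrieval discrimination index in
#'   `[-100, 100]`; encoding sessions are generated with expectation 0.
#' @param seed Integer seed.
#' @return A list of class `behavior_sim_params`.
#' @export
behavior_sim_params <- function(n_bouts = 20, mean_bout = 0.5,
                                preference = 0, seed = 1L) {
  stopifnot(n_bouts >= 0, mean_bout > 0,
            preference >= -100, preference <= 100)
  structure(as.list(environment()), class = "behavior_sim_params")
}

#' Simulate an encoding/retrieval session pair
#'
#' Bout durations are exponential; each bout is assigned to the novel
#' object with probability `(1 + preference/100) / 2` during retrieval
#' and 1/2 during encoding, so the expected retrieval DI equals
#' `preference` and the expected encoding DI is 0.
#'
#' @param params A [behavior_sim_params()] object.
#' @param task `"OLM"`, `"ORM"`, or `"OdorRM"`.
#' @param animal_id,genotype Metadata copied into the records.
#' @return A list with `encoding` and `retrieval` [session_record()]s
#'   and `truth` (`expected_di`).  With `n_bouts = 0` the records are
#'   empty and un-scorable.
#' @export
simulate_behavior_session <- function(params, task = "OLM",
                                      animal_id = "m01",
                                      genotype = "opsin+") {
  stopifnot(inherits(params, "behavior_sim_params"))
  task <- match.arg(task, c("OLM", "ORM", "OdorRM"))
  gen_phase <- function(phase, p_novel) {
    n <- params$n_bouts
    if (n == 0) {
      bouts <- tibble::tibble(object = character(0), start = numeric(0),
                              duration = numeric(0))
    } else {
      durations <- stats::rexp(n, 1 / params$mean_bout)
      obj <- ifelse(stats::runif(n) < p_novel, "novel", "familiar")
      gaps <- stats::rexp(n, 1 / 10)
      starts <- cumsum(gaps) + c(0, cumsum(durations[-n]))
      bouts <- tibble::tibble(object = obj, start = starts,
                              duration = durations)
    }
    session_record(bouts, animal_id, genotype, task, phase)
  }
  .with_seed(params$seed, {
    p <- (1 + params$preference / 100) / 2
    enc <- gen_phase("encoding", 0.5)
    ret <- gen_phase("retrieval", p)
    list(encoding = enc, retrieval = ret,
         truth = list(expected_di = params$preference))
  })
}
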