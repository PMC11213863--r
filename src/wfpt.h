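#ifndef AVDDM_WFPT_H
#define AVDDM_WFPT_H

double avddm_fpt_std(double u, double w, double eps);
double avddm_wfpt_pdf(double t, int upper, double v, double a, double tau,
                      double w, double eps);
double avddm_p_upper(double v, double a, double w);

#endif
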