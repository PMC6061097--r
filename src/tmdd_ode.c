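/* Quasi-equilibrium TMDD right-hand side for deSolve.
 *
 * Integrates NBLK independent model instances ("blocks") in one call so
 * that sensitivity and per-subject solves can be batched.  Each block has
 * three states: depot amount (nmol), total drug concentration (nM) and
 * total target concentration (nM).
 *
 * Parameter vector layout (padded to a fixed length from R):
 *   parms[0]            number of active blocks (<= TMDD_MAXBLK)
 *   parms[1 + 8*b + k]  block b, k = 0..7:
 *                       ka, V, keO (CL_OMA/V), keI (CL_IGE/V),
 *                       keC (CL_COMP/V), KD, R0 (nM), alpha
 */
#include <R.h>
#include <math.h>

#define TMDD_MAXBLK 128
#define TMDD_NPAR   (1 + 8 * TMDD_MAXBLK)

static double parms[TMDD_NPAR];

void tmdd_init(void (*odeparms)(int *, double *))
{
    int n = TMDD_NPAR;
    odeparms(&n, parms);
}

/* free drug from the quasi-equilibrium quadratic, numerically stable branch */
static double qe_free_drug(double dtot, double rtot, double kd)
{
    double b = dtot - rtot - kd;
    double disc = sqrt(b * b + 4.0 * kd * dtot);
    if (b <= 0.0)
        return (disc - b > 0.0) ? 2.0 * kd * dtot / (disc - b) : 0.0;
    return 0.5 * (b + disc);
}

void tmdd_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    int nblk = (int) parms[0];
    for (int b = 0; b < nblk; b++) {
        const double *p = parms + 1 + 8 * b;
        double ka = p[0], V = p[1], keO = p[2], keI = p[3];
        double keC = p[4], kd = p[5], r0 = p[6], alpha = p[7];

        double A    = y[3 * b];
        double dtot = y[3 * b + 1] > 0.0 ? y[3 * b + 1] : 0.0;
        double rtot = y[3 * b + 2] > 0.0 ? y[3 * b + 2] : 0.0;

        double dfree = qe_free_drug(dtot, rtot, kd);
        double cmplx = dtot - dfree;
        double rfree = rtot - cmplx;
        if (rfree < 0.0) rfree = 0.0;

        /* target loss: keI * R0 * (rfree/R0)^alpha, synthesis fixes R0 */
        double loss = (rfree > 0.0) ? keI * r0 * pow(rfree / r0, alpha) : 0.0;

        ydot[3 * b]     = -ka * A;
        ydot[3 * b + 1] = ka * A / V - keO * dfree - keC * cmplx;
        ydot[3 * b + 2] = keI * r0 - loss - keC * cmplx;
    }
}
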