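/* Compiled right-hand side of the reduced chemostat model, for deSolve.
 *
 * The model is passed once per integration through drum_set_rhs_data() as a
 * flat double vector (see pack_rhs_parms() on the R side):
 *
 *   [0] ns   [1] nr   [2] D   [3] biomass index (0-based)
 *   [4] light form (0 square, 1 truncated sine)
 *   [5] period  [6] day_length  [7] I_max  [8] phase
 *   [9 .. 9+ns*nr)          K' column-major
 *   [.. +ns)                 M_in
 *   [.. +ns)                 clamp mask (1 = held constant)
 *   [.. +6*nr)               per reaction: form, e1, e2, e3, p1, p2
 *
 * Law forms: 0 zero; 1 k*I; 2 k*X1; 3 k*X1 - k'*X2;
 *            4 k*X1*X2 - k'*X3; 5 k*X1*X2*X3.
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>

static double *drum_p = NULL;
static int drum_plen = 0;

SEXP drum_set_rhs_data(SEXP parms)
{
    int n = LENGTH(parms);
    if (drum_p != NULL) {
        free(drum_p);
        drum_p = NULL;
    }
    drum_p = (double *) malloc(n * sizeof(double));
    if (drum_p == NULL)
        error("cannot allocate RHS data");
    memcpy(drum_p, REAL(parms), n * sizeof(double));
    drum_plen = n;
    return R_NilValue;
}

void drum_initmod(void (*odeparms)(int *, double *))
{
    /* model data arrives through drum_set_rhs_data(), not odeparms */
}

static double state_at(const double *y, int idx)
{
    double v = y[idx];
    return v > 0.0 ? v : 0.0;
}

void drum_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    if (drum_p == NULL)
        error("RHS data not initialised");
    const double *p = drum_p;
    int ns = (int) p[0];
    int nr = (int) p[1];
    double D = p[2];
    int ib = (int) p[3];
    int lform = (int) p[4];
    double period = p[5], day_len = p[6], imax = p[7], phase = p[8];
    const double *K = p + 9;
    const double *min = K + (size_t) ns * nr;
    const double *clamp = min + ns;
    const double *law = clamp + ns;

    if (*neq != ns)
        error("state dimension mismatch in compiled RHS");

    /* light forcing */
    double tt = fmod(*t - phase, period);
    if (tt < 0) tt += period;
    double I = 0.0;
    if (tt < day_len) {
        if (lform == 0)
            I = imax;
        else
            I = imax * sin(M_PI * tt / day_len);
        if (I < 0) I = 0;
    }

    double B = state_at(y, ib);

    for (int i = 0; i < ns; i++)
        ydot[i] = -D * y[i] + D * min[i];

    for (int j = 0; j < nr; j++) {
        const double *lj = law + 6 * j;
        int form = (int) lj[0];
        int e1 = (int) lj[1], e2 = (int) lj[2], e3 = (int) lj[3];
        double k1 = lj[4], k2 = lj[5];
        double a = 0.0;
        switch (form) {
        case 0: a = 0.0; break;
        case 1: a = k1 * I; break;
        case 2: a = k1 * state_at(y, e1); break;
        case 3: a = k1 * state_at(y, e1) - k2 * state_at(y, e2); break;
        case 4: a = k1 * state_at(y, e1) * state_at(y, e2)
                    - k2 * state_at(y, e3); break;
        case 5: a = k1 * state_at(y, e1) * state_at(y, e2)
                    * state_at(y, e3); break;
        default: error("unknown kinetic form code %d", form);
        }
        if (a != 0.0) {
            double ab = a * B;
            const double *Kj = K + (size_t) ns * j;
            for (int i = 0; i < ns; i++)
                ydot[i] += Kj[i] * ab;
        }
    }

    for (int i = 0; i < ns; i++)
        if (clamp[i] != 0.0)
            ydot[i] = 0.0;
}
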